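#' A-posteriori seeding densities of six aggregating carcinoma lines
#'
#' Reference seeding densities (counted a posteriori from the seed frame)
#' at which six aggregating cancer cell lines — PC-3, MDA-MB-231, ACHN,
#' MG-63, NCI-H23 and Hs 746T — undergo collective aggregation in 3D gel
#' assays. Useful as realistic density inputs and for spacing design rules.
#'
#' @return A tibble with `cell_line` and `density` (cells/mm^3).
#' @examples
#' aggregating_line_densities()
#' @export
aggregating_line_densities <- function() {
  tibble(
    cell_line = c("PC-3", "MDA-MB-231", "ACHN", "MG-63", "NCI-H23", "Hs 746T"),
    density = c(31, 22.2, 35.1, 84.2, 36.2, 90.4)
  )
}

#' Mean inter-cell spacing at a seeding density
#'
#' The characteristic spacing of a uniform seeding, `density^(-1/3)`,
#' converted to micrometres. At 10-100 cells/mm^3 cells sit hundreds of
#' micrometres apart — far beyond cell size, so aggregation requires
#' migration.
#'
#' @param density Seeding density (cells/mm^3); vectorised.
#' @return Spacing (um).
#' @examples
#' mean_spacing(90.4)
#' @export
mean_spacing <- function(density) {
  stopifnot(all(density > 0))
  1000 * density^(-1 / 3)
}

#' Expected nearest-neighbour distance of a Poisson seeding
#'
#' Closed form for uniform (Poisson) random seeding in 3D:
#' `Gamma(4/3) * (4 pi rho / 3)^(-1/3)`, i.e. about
#' `0.554 * rho^(-1/3)`.
#'
#' @param density Seeding density (cells/mm^3); vectorised.
#' @return Expected nearest-neighbour distance (um).
#' @export
expected_nn_distance <- function(density) {
  stopifnot(all(density > 0))
  rho <- density * 1e-9  # cells / um^3
  gamma(4 / 3) * (4 * pi * rho / 3)^(-1 / 3)
}
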