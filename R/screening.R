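#' Select a hit-calling threshold from cell-free control panels
#'
#' Chooses the smallest intensity threshold at which the number of control
#' entries strictly above it does not exceed `tolerate_hits`. With the
#' default `tolerate_hits = 0` this is the maximum intensity observed across
#' all control panels: the common threshold that minimises (to zero) the
#' number of hits called in cell-free, serum-free and matrix-free media.
#'
#' @param controls A data frame of control-panel measurements with columns
#'   `analyte` and `intensity` (a `sample` column may distinguish panels but
#'   is not required).
#' @param tolerate_hits Maximum number of control entries allowed above the
#'   threshold; default 0.
#' @return The threshold (intensity units).
#' @export
select_threshold <- function(controls, tolerate_hits = 0) {
  controls <- as_tibble(controls)
  stopifnot("intensity" %in% names(controls))
  v <- controls$intensity
  if (length(v) == 0) abort("no control measurements supplied")
  if (any(v < 0)) abort("intensities must be non-negative")
  if (tolerate_hits <= 0) return(max(v))
  sorted <- sort(v, decreasing = TRUE)
  if (tolerate_hits >= length(sorted)) return(0)
  # smallest threshold with at most k entries strictly above it
  sorted[tolerate_hits + 1]
}

#' Call analyte hits in a conditioned-medium panel
#'
#' Analytes whose intensity exceeds the control-derived threshold, minus any
#' analytes that also exceeded it in cell-free controls (the
#' control-positive set).
#'
#' @param sample A data frame with columns `analyte` and `intensity`.
#' @param threshold Intensity threshold from [select_threshold()].
#' @param control_positive Character vector of analytes to filter out.
#' @return Character vector of hit analytes.
#' @export
call_hits <- function(sample, threshold, control_positive = character()) {
  sample <- as_tibble(sample)
  stopifnot(all(c("analyte", "intensity") %in% names(sample)))
  if (anyDuplicated(sample$analyte)) {
    abort("analyte ids must be unique within a sample")
  }
  hits <- sample$analyte[sample$intensity > threshold]
  setdiff(hits, control_positive)
}

#' Overlap summary of several hit sets
#'
#' Counts every intersection region of the supplied sets (the regions of an
#' Euler-Venn diagram), the fraction shared by all sets relative to their
#' union, and pairwise Jaccard fractions.
#'
#' @param hit_sets A named list (length >= 2) of character vectors.
#' @return A list with `regions` (tibble: one row per membership pattern
#'   with its count), `shared_fraction` (`|intersection| / |union|`) and
#'   `pairwise` (tibble of pairwise Jaccard fractions).
#' @export
overlap_summary <- function(hit_sets) {
  stopifnot(is.list(hit_sets), length(hit_sets) >= 2)
  if (is.null(names(hit_sets)) || any(names(hit_sets) == "")) {
    names(hit_sets) <- paste0("set", seq_along(hit_sets))
  }
  universe <- unique(unlist(hit_sets))
  membership <- vapply(hit_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(r) {
    paste(names(hit_sets)[r], collapse = "&")
  })
  regions <- as_tibble(table(pattern), .name_repair = ~ c("region", "count"))
  regions$count <- as.integer(regions$count)
  inter <- Reduce(intersect, hit_sets)
  shared <- if (length(universe) == 0) NA_real_ else {
    length(inter) / length(universe)
  }
  combs <- utils::combn(names(hit_sets), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(combs)), function(i) {
    a <- hit_sets[[combs[1, i]]]; b <- hit_sets[[combs[2, i]]]
    u <- length(union(a, b))
    tibble(set_a = combs[1, i], set_b = combs[2, i],
           jaccard = if (u == 0) NA_real_ else length(intersect(a, b)) / u)
  })
  list(regions = regions, shared_fraction = shared, pairwise = pairwise)
}

#' Transwell migration statistics: fold over control and one-tailed Welch test
#'
#' Normalises per-membrane migration measures by the median of the
#' serum-free control group (fold over control) and tests whether the
#' condition group migrates more than the control with an unpaired
#' one-tailed t-test with Welch's correction (unequal variances,
#' Welch-Satterthwaite degrees of freedom).
#'
#' @param data A data frame with one row per membrane.
#' @param measure Column (tidy-eval) holding the migrated-cell measure
#'   (count or segmented area).
#' @param group Column (tidy-eval) holding the group labels.
#' @param control Label of the control group; default `"SF"`.
#' @return A tibble with one row per non-control condition: median fold
#'   over control, Welch `t`, degrees of freedom, one-tailed `p`
#'   (condition greater than control) and group sizes.
#' @export
transwell_stats <- function(data, measure, group, control = "SF") {
  data <- as_tibble(data)
  m <- eval_tidy(enquo(measure), data)
  g <- as.character(eval_tidy(enquo(group), data))
  if (!control %in% g) abort(sprintf("control group '%s' not found", control))
  ctrl <- m[g == control]
  if (length(ctrl) < 2) abort("control group needs at least 2 membranes")
  ctrl_med <- median(ctrl)
  if (ctrl_med == 0) abort("zero control median: folds undefined")
  conditions <- setdiff(unique(g), control)
  purrr::map_dfr(conditions, function(cond) {
    x <- m[g == cond]
    if (length(x) < 2) abort(sprintf("group '%s' needs at least 2 membranes", cond))
    tt <- t.test(x, ctrl, alternative = "greater", var.equal = FALSE)
    tibble(condition = cond,
           fold_median = median(x / ctrl_med),
           t = unname(tt$statistic),
           df = unname(tt$parameter),
           p_value = tt$p.value,
           n_condition = length(x),
           n_control = length(ctrl))
  })
}
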