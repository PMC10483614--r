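#' Read and write series, masks, stacks and reports
#'
#' CSV round-trip for count and area series, TIFF round-trip for masks
#' (8-bit label images, exact) and stacks (32-bit float), and JSON
#' round-trip for assay reports. Physical metadata (pixel size, z step,
#' intensity scaling) travels in a small JSON sidecar `<path>.meta.json`
#' next to each TIFF; readers fall back to unit pixel size without it.
#' CSV column names at the interface are `time_days`, `count`,
#' `density_cells_per_mm3` and `area_um2`.
#'
#' @param series,mask,stack,report Object to write.
#' @param path File path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @name cdm_io
NULL

#' @rdname cdm_io
#' @export
write_count_series <- function(series, path) {
  stopifnot(all(c("time_days", "count") %in% names(series)))
  out <- tibble(time_days = series$time_days, count = series$count)
  if ("density" %in% names(series)) {
    out$density_cells_per_mm3 <- series$density
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname cdm_io
#' @export
read_count_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_days", "count") %in% names(df))) {
    abort(sprintf("%s: expected columns time_days, count", path))
  }
  out <- tibble(time_days = df$time_days, count = df$count)
  if ("density_cells_per_mm3" %in% names(df)) {
    out$density <- df$density_cells_per_mm3
  }
  out
}

#' @rdname cdm_io
#' @export
write_area_series <- function(series, path) {
  stopifnot(all(c("time_days", "area_um2") %in% names(series)))
  readr::write_csv(tibble(time_days = series$time_days,
                          area_um2 = series$area_um2), path)
  invisible(path)
}

#' @rdname cdm_io
#' @export
read_area_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_days", "area_um2") %in% names(df))) {
    abort(sprintf("%s: expected columns time_days, area_um2", path))
  }
  tibble(time_days = df$time_days, area_um2 = df$area_um2)
}

#' @rdname cdm_io
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "class_mask"))
  tiff::writeTIFF(mask$labels / 255, path, bits.per.sample = 8)
  write_tiff_meta(path, list(pixel_size = mask$pixel_size,
                             type = "class_mask"))
  invisible(path)
}

#' @rdname cdm_io
#' @export
read_mask_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- read_tiff_meta(path)
  labels <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  class_mask(labels, pixel_size = meta$pixel_size %||% 1)
}

#' @rdname cdm_io
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  vmax <- max(stack$voxels, 1e-12)
  vmin <- min(stack$voxels, 0)
  scale <- vmax - vmin
  if (scale == 0) scale <- 1
  pages <- lapply(seq_len(dim(stack$voxels)[3]), function(z) {
    (stack$voxels[, , z] - vmin) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  write_tiff_meta(path, list(pixel_size = stack$pixel_size,
                             z_step = stack$z_step, offset = vmin,
                             scale = scale, type = "image_stack"))
  invisible(path)
}

#' @rdname cdm_io
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- read_tiff_meta(path)
  vox <- array(0, c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) vox[, , z] <- as.matrix(pages[[z]])
  vox <- vox * (meta$scale %||% 1) + (meta$offset %||% 0)
  image_stack(vox, pixel_size = meta$pixel_size %||% 1,
              z_step = meta$z_step %||% 1)
}

write_tiff_meta <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
}

read_tiff_meta <- function(path) {
  mp <- paste0(path, ".meta.json")
  if (!file.exists(mp)) return(list())
  tryCatch(jsonlite::fromJSON(mp), error = function(e) list())
}

#' @rdname cdm_io
#' @export
write_assay_report <- function(report, path) {
  stopifnot(inherits(report, "assay_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname cdm_io
#' @export
read_assay_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  obj$assays <- as_tibble(obj$assays)
  structure(obj, class = "assay_report")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path A `.yaml`/`.yml` or `.json` file whose top-level keys match
#'   the arguments of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort(sprintf("%s: unsupported config format '%s'", path, ext))
  }
  do.call(pipeline_config, raw)
}
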