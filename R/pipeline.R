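#' Pipeline configuration
#'
#' Bundles the simulator, renderer and analysis settings of an end-to-end
#' run: simulate replicated assays over one or more seeding densities,
#' optionally push every frame through the imaging chain
#' (render -> EDF -> segment -> filter -> count), fit kinetics and growth,
#' and classify directionality across densities. Every default can be
#' overridden; all randomness derives from the single `seed`.
#'
#' @param simulation Named list of [sim_config()] overrides shared by all
#'   assays (everything except `density` and `seed`).
#' @param render Named list of [render_config()] overrides (used when
#'   `use_imaging = TRUE`).
#' @param analysis Named list: `kernel_width` (um, EDF), `opening_radius`
#'   (um), `min_radius` (um), `intensity_threshold` (`"auto"` or numeric)
#'   and `use_imaging` (logical; `FALSE` reads counts/areas from simulator
#'   ground truth, `TRUE` measures them from rendered stacks).
#' @param densities Seeding densities to run (cells/mm^3).
#' @param replicates Assays per density.
#' @param seed Global integer seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(simulation = list(),
                            render = list(),
                            analysis = list(),
                            densities = c(15, 30, 60, 120),
                            replicates = 1,
                            seed = 1L) {
  analysis_defaults <- list(kernel_width = 8, opening_radius = 15,
                            min_radius = 50, intensity_threshold = "auto",
                            use_imaging = FALSE)
  structure(
    list(simulation = simulation, render = render,
         analysis = modifyList(analysis_defaults, as.list(analysis)),
         densities = densities, replicates = replicates,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# 31-polynomial rolling hash of a deparsed object; stable identifier for
# configs in reports and logs
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

pipeline_log <- function(con, stage, seed, hash, ...) {
  if (is.null(con)) return(invisible())
  rec <- c(list(stage = stage, seed = seed, config_hash = hash), list(...))
  writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE)), con)
}

#' Run the end-to-end aggregation pipeline
#'
#' For each density and replicate: simulate an assay, derive object-count
#' and projected-area series (from ground truth, or through the full
#' imaging chain when `use_imaging = TRUE`), fit the count sigmoid (halving
#' time, lag time, density fraction), fit exponential growth when growth is
#' on, and record the aggregating fraction. Across densities, halving times
#' are regressed on density to classify motion as directed or random.
#' Deterministic for a fixed config and seed. Stage failures abort with a
#' stage-tagged error; artifacts already written are left in place.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, per-assay series (CSV),
#'   merge logs (JSON), the report (JSON) and a JSON-lines log are written
#'   with stable filenames.
#' @return An `assay_report`: `assays` (one row per assay), `directionality`
#'   (slope, SE, label, or `NULL` when not estimable), `config_hash`,
#'   `seed`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(unclass(config))
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(out_dir, "pipeline_log.jsonl"), open = "wt")
    on.exit(close(log_con), add = TRUE)
  }
  pipeline_log(log_con, "start", config$seed, hash,
               densities = config$densities, replicates = config$replicates)
  an <- config$analysis
  grid <- tidyr::expand_grid(density = config$densities,
                             replicate = seq_len(config$replicates))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    density <- grid$density[i]
    replicate <- grid$replicate[i]
    run_seed <- (config$seed * 7919L + i) %% .Machine$integer.max
    sim_args <- modifyList(as.list(config$simulation),
                           list(density = density, seed = run_seed))
    truth <- with_stage("simulate", {
      run_assay(do.call(sim_config, sim_args),
                keep_states = isTRUE(an$use_imaging))
    })
    if (isTRUE(an$use_imaging)) {
      series <- with_stage("imaging", {
        measure_frames(truth, config$render, an, run_seed)
      })
      cs <- tibble(time_days = series$time_days, count = series$count,
                   density = density)
      as <- tibble(time_days = series$time_days, area_um2 = series$area_um2)
    } else {
      cs <- count_series(truth)
      as <- area_series(truth)
    }
    fit <- with_stage("kinetics", fit_count_sigmoid(cs))
    gfit <- if (truth$config$T_d_true > 0 && all(as$area_um2 > 0)) {
      with_stage("growth", fit_growth(as))
    } else {
      NULL
    }
    rows[[i]] <- tibble(
      density = density, replicate = replicate, seed = run_seed,
      n0_seeded = truth$initial_count,
      fit_status = fit$status,
      n0 = fit$n0, b = fit$b, t_m = fit$t_m, s = fit$s,
      t_half = fit$t_half, t_half_crossing = crossing_time(cs),
      t_lag = fit$t_lag,
      density_fraction = fit$density_fraction,
      T_d = if (is.null(gfit)) NA_real_ else gfit$T_d,
      aggregating_fraction = aggregating_fraction(truth)
    )
    if (!is.null(out_dir)) {
      tag <- sprintf("density%03d_rep%02d", round(density), replicate)
      write_count_series(cs, file.path(out_dir, paste0("counts_", tag, ".csv")))
      write_area_series(as, file.path(out_dir, paste0("areas_", tag, ".csv")))
      jsonlite::write_json(truth$merges,
                           file.path(out_dir, paste0("merges_", tag, ".json")),
                           digits = NA)
    }
    pipeline_log(log_con, "assay", config$seed, hash, density = density,
                 replicate = replicate, t_half = fit$t_half)
  }
  assays <- bind_rows(rows)
  directionality <- NULL
  # the scaling regression uses the model-free crossing halving time, which
  # stays well defined when the logistic initial asymptote is weakly
  # identified (lag-free decays)
  defined <- assays[is.finite(assays$t_half_crossing) &
                      assays$t_half_crossing > 0, , drop = FALSE]
  if (nrow(defined) >= 3 &&
      max(defined$density) / min(defined$density) >= 2) {
    dfit <- with_stage(
      "directionality",
      fit_directionality(tibble(density = defined$density,
                                t_half = defined$t_half_crossing))
    )
    directionality <- list(beta = dfit$beta, beta_se = dfit$beta_se,
                           label = dfit$label, n = dfit$n)
  }
  report <- structure(
    list(assays = assays, directionality = directionality,
         config_hash = hash, seed = config$seed),
    class = "assay_report"
  )
  if (!is.null(out_dir)) {
    write_assay_report(report, file.path(out_dir, "report.json"))
  }
  pipeline_log(log_con, "done", config$seed, hash)
  report
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[stage %s] %s", stage, conditionMessage(e)))
  })
}

# render each kept frame and measure counts/areas through the imaging chain
measure_frames <- function(truth, render_overrides, an, seed) {
  if (is.null(truth$states)) abort("assay was run without keep_states")
  rc <- do.call(render_config, as.list(render_overrides))
  res <- purrr::imap(truth$states, function(state, k) {
    stack <- render_stack(state, rc, seed = seed + k)
    proj <- edf_project(stack, kernel_width = an$kernel_width)
    mask <- segment_classes(proj, intensity_threshold = an$intensity_threshold,
                            opening_radius = an$opening_radius)
    mask <- filter_small(mask, min_radius = an$min_radius)
    tibble(time_days = state$time_days,
           count = count_objects(mask),
           area_um2 = total_area(mask))
  })
  bind_rows(res)
}

#' @export
print.assay_report <- function(x, ...) {
  cat("<assay_report>", nrow(x$assays), "assays | seed", x$seed,
      "| config", x$config_hash, "\n")
  if (!is.null(x$directionality)) {
    cat("  directionality: beta =", format(x$directionality$beta, digits = 3),
        "->", x$directionality$label, "\n")
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `assay_report`.
#' @param ... Unused.
#' @export
tidy.assay_report <- function(x, ...) x$assays

#' @rdname run_pipeline
#' @export
glance.assay_report <- function(x, ...) {
  tibble(
    n_assays = nrow(x$assays),
    beta = x$directionality$beta %||% NA_real_,
    label = x$directionality$label %||% NA_character_,
    median_t_half = median(x$assays$t_half, na.rm = TRUE),
    median_density_fraction = median(x$assays$density_fraction, na.rm = TRUE),
    seed = x$seed, config_hash = x$config_hash
  )
}
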