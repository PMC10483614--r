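#' Construct a cluster state
#'
#' A `cluster_state` holds the positions, per-cluster cell counts and derived
#' radii of all live clusters at one simulated time point. Radii follow the
#' volume-conserving rule `r_i = r_cell * n_i^(1/3)`.
#'
#' @param clusters A data frame with columns `id`, `x`, `y`, `z` (um) and
#'   `n_cells` (positive reals).
#' @param r_cell Single-cell radius (um).
#' @param box_edge Edge of the cubic assay volume (um).
#' @param time_days Simulated time (days).
#' @return An object of class `cluster_state`.
#' @export
cluster_state <- function(clusters, r_cell = 10, box_edge = 1000,
                          time_days = 0) {
  clusters <- as_tibble(clusters)
  stopifnot(all(c("id", "x", "y", "z", "n_cells") %in% names(clusters)))
  if (anyDuplicated(clusters$id)) abort("cluster ids must be unique")
  if (any(clusters$n_cells <= 0)) abort("cell counts must be positive")
  clusters$radius <- r_cell * clusters$n_cells^(1 / 3)
  structure(
    list(clusters = clusters, r_cell = r_cell, box_edge = box_edge,
         time_days = time_days,
         next_id = if (nrow(clusters)) max(clusters$id) + 1L else 1L),
    class = "cluster_state"
  )
}

#' @export
print.cluster_state <- function(x, ...) {
  cat("<cluster_state>", nrow(x$clusters), "clusters |",
      sum(x$clusters$n_cells), "cells | t =", format(x$time_days, digits = 4),
      "d\n")
  invisible(x)
}

#' @export
as_tibble.cluster_state <- function(x, ...) x$clusters

#' Seed clusters uniformly at random in the assay volume
#'
#' Places single cells (clusters with `n_i = 1`) uniformly at random in the
#' cubic gel volume. The realised count is Poisson with mean
#' `density x volume`, emulating a-posteriori counted seeding densities.
#'
#' @param config A [sim_config()].
#' @return A `cluster_state` at time 0.
#' @examples
#' st <- seed_clusters(sim_config(density = 31, seed = 7))
#' nrow(st$clusters)
#' @export
seed_clusters <- function(config) {
  validate_sim_config(config)
  if (config$box_edge <= 0) abort("box volume must be positive")
  set.seed(config$seed)
  seed_clusters_impl(config)
}

seed_clusters_impl <- function(config) {
  vol_mm3 <- (config$box_edge / 1000)^3
  n <- rpois(1L, config$density * vol_mm3)
  cl <- tibble(
    id = seq_len(n),
    x = runif(n, 0, config$box_edge),
    y = runif(n, 0, config$box_edge),
    z = runif(n, 0, config$box_edge),
    n_cells = rep(1, n)
  )
  cluster_state(cl, r_cell = config$r_cell, box_edge = config$box_edge)
}

#' Quasi-steady attractant field of secreting clusters
#'
#' Each cluster secretes a diffusible attractant at rate `S` per cell; in the
#' quasi-steady limit a point source of strength `S * n_i` generates the
#' profile `S * n_i / (4 pi D |x - x_i|)`, and fields superpose. The gradient
#' is the analytic derivative. One source (typically the querying cluster
#' itself) can be excluded to avoid the self-attraction singularity.
#'
#' @param state A `cluster_state`.
#' @param query Numeric length-3 point (um).
#' @param exclude_id Optional cluster id excluded from the superposition.
#' @param S,D Secretion rate per cell and attractant diffusion coefficient.
#' @return A list with `concentration` (scalar) and `gradient` (length-3).
#' @export
attractant_field <- function(state, query, exclude_id = NULL, S = 1, D = 100) {
  cl <- state$clusters
  if (!is.null(exclude_id)) cl <- cl[cl$id != exclude_id, , drop = FALSE]
  if (nrow(cl) == 0) {
    return(list(concentration = 0, gradient = c(0, 0, 0)))
  }
  dx <- query[1] - cl$x
  dy <- query[2] - cl$y
  dz <- query[3] - cl$z
  d2 <- dx^2 + dy^2 + dz^2
  if (any(d2 == 0)) abort("query point coincides with an included source")
  d <- sqrt(d2)
  k <- S * cl$n_cells / (4 * pi * D)
  conc <- sum(k / d)
  g <- -c(sum(k * dx / d^3), sum(k * dy / d^3), sum(k * dz / d^3))
  list(concentration = conc, gradient = g)
}

# reflect coordinates into [0, box] (gel walls)
reflect_into_box <- function(p, box) {
  p <- p %% (2 * box)
  ifelse(p > box, 2 * box - p, p)
}

# --- fast core: plain-matrix representation used by the stepping loop ---
# core = list(pos [m x 3], n [m], id [m], next_id, time_h)

state_to_core <- function(state) {
  cl <- state$clusters
  list(pos = cbind(cl$x, cl$y, cl$z), n = cl$n_cells,
       id = as.integer(cl$id), next_id = state$next_id,
       time_h = state$time_days * 24)
}

core_to_state <- function(core, config) {
  m <- length(core$n)
  st <- cluster_state(
    tibble(id = core$id, x = core$pos[, 1], y = core$pos[, 2],
           z = core$pos[, 3], n_cells = core$n),
    r_cell = config$r_cell, box_edge = config$box_edge,
    time_days = core$time_h / 24
  )
  st$next_id <- core$next_id
  st
}

# merge all contacting pairs (|x_i - x_j| <= r_i + r_j), chaining until no
# contact remains; merge events appended to core$merges (numeric rows:
# time_days, id_a, id_b, new_id)
core_merge <- function(core, r_cell) {
  merges <- NULL
  repeat {
    m <- length(core$n)
    if (m < 2) break
    r <- r_cell * core$n^(1 / 3)
    dmat <- as.matrix(stats::dist(core$pos))
    diag(dmat) <- Inf
    hit <- which(dmat <= outer(r, r, "+"), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    if (nrow(hit) == 0) break
    i <- hit[1, 1]; j <- hit[1, 2]
    ni <- core$n[i]; nj <- core$n[j]
    merges <- rbind(merges, c(core$time_h / 24, core$id[i], core$id[j],
                              core$next_id))
    core$pos[i, ] <- (ni * core$pos[i, ] + nj * core$pos[j, ]) / (ni + nj)
    core$n[i] <- ni + nj
    core$id[i] <- core$next_id
    core$next_id <- core$next_id + 1L
    keep <- -j
    core$pos <- core$pos[keep, , drop = FALSE]
    core$n <- core$n[keep]
    core$id <- core$id[keep]
  }
  core$merges <- merges
  core
}

core_step <- function(core, config) {
  m <- length(core$n)
  if (m > 0) {
    if (config$mode == "directed" && config$v0 > 0 && m > 1) {
      g <- gradient_matrix(core$pos, core$n, config$S, config$D)
      gn <- sqrt(rowSums(g^2))
      if (config$response == "constant") {
        step_len <- ifelse(gn > 0, config$v0 * config$dt, 0)
      } else {
        step_len <- pmin(config$chemo_gain * gn, config$v0) * config$dt
      }
      gn[gn == 0] <- 1
      core$pos <- core$pos + (step_len / gn) * g
    } else if (config$mode == "random" && config$D_c > 0) {
      sdd <- sqrt(2 * config$D_c * config$dt)
      core$pos <- core$pos + matrix(rnorm(3 * m, 0, sdd), m, 3)
    }
    if (config$T_d_true > 0) {
      core$n <- core$n * 2^(config$dt / 24 / config$T_d_true)
    }
    core$pos <- reflect_into_box(core$pos, config$box_edge)
  }
  core$time_h <- core$time_h + config$dt
  core_merge(core, config$r_cell)
}

gradient_matrix <- function(pos, n, S, D) {
  m <- nrow(pos)
  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  dz <- outer(pos[, 3], pos[, 3], "-")
  d2 <- dx * dx + dy * dy + dz * dz
  diag(d2) <- Inf
  w <- matrix(S * n / (4 * pi * D), m, m, byrow = TRUE) / d2^1.5
  cbind(-rowSums(dx * w), -rowSums(dy * w), -rowSums(dz * w))
}

#' Advance a cluster state by one time step
#'
#' Applies, in order: motion (directed at constant speed `v0` up the
#' own-source-excluded attractant gradient, or Brownian with per-axis
#' variance `2 D_c dt`), exponential growth (`n_i` multiplied by
#' `2^(dt / T_d)` when growth is on), reflecting boundary conditions, and
#' contact merging. Merging pairs are replaced by a single cluster at the
#' cell-count-weighted centroid with `n = n_i + n_j`; radii follow from the
#' volume-conserving radius rule. Merge events of the step are attached as
#' attribute `"merges"`.
#'
#' @param state A `cluster_state`.
#' @param config A [sim_config()].
#' @return The advanced `cluster_state`.
#' @export
step_clusters <- function(state, config) {
  core <- core_step(state_to_core(state), config)
  out <- core_to_state(core, config)
  attr(out, "merges") <- merges_tibble(core$merges)
  out
}

merges_tibble <- function(m) {
  if (is.null(m)) {
    return(tibble(time_days = numeric(), id_a = integer(),
                  id_b = integer(), new_id = integer()))
  }
  tibble(time_days = m[, 1], id_a = as.integer(m[, 2]),
         id_b = as.integer(m[, 3]), new_id = as.integer(m[, 4]))
}

#' Run a full simulated aggregation assay
#'
#' Seeds clusters, advances the state over the configured duration, and
#' records object-count and projected-area series at the frame interval
#' together with the full merge log. The projected area per frame is
#' `sum(pi r_i^2)` over live clusters. Identical configurations (including
#' the seed) give bit-identical results.
#'
#' @param config A [sim_config()].
#' @param stop_fraction If positive, the assay stops early once the object
#'   count drops to this fraction of the initial count; useful for halving
#'   time measurements where the late plateau is not needed. Default 0
#'   (run the full duration).
#' @param keep_states Keep the full `cluster_state` of every recorded frame
#'   (element `states`), e.g. for rendering an image series. Default `FALSE`.
#' @return An object of class `assay_truth` with elements `frames`
#'   (tibble: `frame`, `time_days`, `n_objects`, `total_area_um2`),
#'   `merges` (tibble: `time_days`, `id_a`, `id_b`, `new_id`),
#'   `aggregating_ids` (seed-frame ids whose lineage merged at least once),
#'   `initial_count`, `final_state` and `config`.
#' @examples
#' tr <- run_assay(sim_config(density = 20, duration = 5, seed = 3))
#' tr$frames
#' @export
run_assay <- function(config, stop_fraction = 0, keep_states = FALSE) {
  validate_sim_config(config)
  set.seed(config$seed)
  state0 <- seed_clusters_impl(config)
  core <- state_to_core(state0)
  states <- if (keep_states) list(state0) else NULL
  n0 <- length(core$n)
  # members[[as.character(id)]] = seed ids contained in that cluster
  members <- as.list(setNames(as.list(core$id), core$id))
  aggregating <- integer(0)
  area_of <- function(core, r_cell) sum(pi * (r_cell * core$n^(1 / 3))^2)
  frame_time <- c(0)
  frame_count <- c(n0)
  frame_area <- c(area_of(core, config$r_cell))
  merges <- NULL
  n_steps <- ceiling(config$duration * 24 / config$dt)
  frame_steps <- max(1L, round(config$frame_interval * 24 / config$dt))
  for (k in seq_len(n_steps)) {
    core <- core_step(core, config)
    mg <- core$merges
    if (!is.null(mg)) {
      merges <- rbind(merges, mg)
      for (i in seq_len(nrow(mg))) {
        ka <- as.character(mg[i, 2]); kb <- as.character(mg[i, 3])
        both <- c(members[[ka]], members[[kb]])
        aggregating <- union(aggregating, both)
        members[[as.character(mg[i, 4])]] <- both
        members[[ka]] <- NULL; members[[kb]] <- NULL
      }
    }
    if (k %% frame_steps == 0 || k == n_steps) {
      frame_time <- c(frame_time, core$time_h / 24)
      frame_count <- c(frame_count, length(core$n))
      frame_area <- c(frame_area, area_of(core, config$r_cell))
      if (keep_states) {
        states[[length(states) + 1L]] <- core_to_state(core, config)
      }
    }
    if (stop_fraction > 0 && length(core$n) <= stop_fraction * n0) {
      if (k %% frame_steps != 0 && k != n_steps) {  # record the stop frame
        frame_time <- c(frame_time, core$time_h / 24)
        frame_count <- c(frame_count, length(core$n))
        frame_area <- c(frame_area, area_of(core, config$r_cell))
        if (keep_states) {
          states[[length(states) + 1L]] <- core_to_state(core, config)
        }
      }
      break
    }
  }
  out <- structure(
    list(frames = tibble(frame = seq_along(frame_time) - 1L,
                         time_days = frame_time,
                         n_objects = as.integer(frame_count),
                         total_area_um2 = frame_area),
         merges = merges_tibble(merges),
         aggregating_ids = sort(aggregating), initial_count = n0,
         final_state = core_to_state(core, config), config = config),
    class = "assay_truth"
  )
  if (keep_states) out$states <- states
  out
}

#' @export
print.assay_truth <- function(x, ...) {
  cat("<assay_truth>", x$initial_count, "seed objects ->",
      nrow(x$final_state$clusters), "after",
      format(max(x$frames$time_days), digits = 4), "d |",
      nrow(x$merges), "merges\n")
  invisible(x)
}

#' Fraction of seeded objects involved in aggregation
#'
#' The fraction of seed-frame objects whose lineage took part in at least
#' one merge event over the assay, the simulator's ground-truth counterpart
#' of the aggregating-cell fraction read off time-lapse series.
#'
#' @param truth An `assay_truth` from [run_assay()].
#' @return A fraction in \[0, 1\].
#' @export
aggregating_fraction <- function(truth) {
  if (truth$initial_count == 0) abort("empty seed frame")
  length(truth$aggregating_ids) / truth$initial_count
}

#' Object-count series of an assay
#'
#' @param truth An `assay_truth`.
#' @return A tibble with `time_days`, `count` and the seeding `density`.
#' @export
count_series <- function(truth) {
  tibble(time_days = truth$frames$time_days,
         count = truth$frames$n_objects,
         density = truth$config$density)
}

#' Projected-area series of an assay
#'
#' @param truth An `assay_truth`.
#' @return A tibble with `time_days` and `area_um2`.
#' @export
area_series <- function(truth) {
  tibble(time_days = truth$frames$time_days,
         area_um2 = truth$frames$total_area_um2)
}

#' Halving time of a count series by threshold crossing
#'
#' First time at which the recorded object count reaches the given fraction
#' of its initial value, linearly interpolated between frames. `NA` when the
#' series never crosses (a non-aggregating assay).
#'
#' @param series A data frame with `time_days` and `count`.
#' @param fraction Crossing fraction of the initial count; default 0.5.
#' @return Time in days, or `NA`.
#' @export
crossing_time <- function(series, fraction = 0.5) {
  stopifnot(all(c("time_days", "count") %in% names(series)))
  target <- series$count[1] * fraction
  k <- which(series$count <= target)[1]
  if (is.na(k)) return(NA_real_)
  if (k == 1L) return(series$time_days[1])
  t1 <- series$time_days[k - 1]; t2 <- series$time_days[k]
  c1 <- series$count[k - 1]; c2 <- series$count[k]
  t1 + (c1 - target) / (c1 - c2) * (t2 - t1)
}

#' Replicated halving-time experiment across seeding densities
#'
#' Runs replicated simulated assays over a set of seeding densities and
#' measures a halving time per assay, the input to [fit_directionality()].
#' Random-mode assays use a fine time step so that Brownian steps stay below
#' the contact scale; both modes record frames every 3 simulated hours so
#' that fast halving at high density is resolved.
#'
#' @param mode `"directed"` or `"random"`.
#' @param densities Seeding densities (cells/mm^3).
#' @param replicates Assays per density.
#' @param duration Assay length (days).
#' @param seed Base seed; assay `j` of density `i` runs with a seed derived
#'   deterministically from it.
#' @param stop_fraction Passed to [run_assay()]; default 0.45 stops shortly
#'   after halving. Set to 0 to run full assays (needed for plateau fits).
#' @param ... Further [sim_config()] overrides.
#' @return A tibble with one row per assay: `density`, `replicate`, `seed`,
#'   `n0`, `t_half` (crossing-based, days) and the `assay` object itself in
#'   a list column when `keep_assays = TRUE`.
#' @param keep_assays Keep the full `assay_truth` objects in a list column.
#' @export
scaling_experiment <- function(mode = c("random", "directed"),
                               densities = c(15, 30, 60, 120),
                               replicates = 20,
                               duration = 28,
                               seed = 1L,
                               stop_fraction = 0.45,
                               keep_assays = FALSE,
                               ...) {
  mode <- match.arg(mode)
  defaults <- if (mode == "random") {
    list(mode = "random", D_c = 1000, dt = 0.05)
  } else {
    list(mode = "directed", v0 = 2, dt = 0.5)
  }
  overrides <- list(...)
  grid <- tidyr::expand_grid(density = densities,
                             replicate = seq_len(replicates))
  res <- pmap(grid, function(density, replicate) {
    run_seed <- (as.integer(seed) * 1009L +
                   match(density, densities) * 131L + replicate) %% .Machine$integer.max
    args <- modifyList(
      c(defaults, list(density = density, duration = duration,
                       frame_interval = 1 / 8, seed = run_seed)),
      overrides
    )
    tr <- run_assay(do.call(sim_config, args), stop_fraction = stop_fraction)
    out <- tibble(density = density, replicate = replicate, seed = run_seed,
                  n0 = tr$initial_count,
                  t_half = crossing_time(count_series(tr)))
    if (keep_assays) out$assay <- list(tr)
    out
  })
  bind_rows(res)
}
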