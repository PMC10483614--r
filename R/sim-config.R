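#' Simulation configuration for a 3D cluster aggregation assay
#'
#' Builds and validates the parameter set of the agent-based assay simulator.
#' Clusters of cells are seeded uniformly at random in a cubic gel volume,
#' move either up the gradient of a self-secreted diffusible attractant
#' (`mode = "directed"`) or by isotropic Brownian motion (`mode = "random"`),
#' optionally grow exponentially, and merge irreversibly on contact.
#'
#' Units are fixed at the interface: lengths in micrometres, seeding density
#' in cells per cubic millimetre, the time step in hours, assay duration and
#' doubling time in days.
#'
#' @param box_edge Edge length of the cubic assay volume (um). Default 1000
#'   (a 1 mm cube of gel).
#' @param density Seeding density (cells per mm^3). Assays in gels are seeded
#'   at roughly 10-100 cells/mm^3.
#' @param mode `"directed"` (constant speed up the attractant gradient) or
#'   `"random"` (Brownian motion).
#' @param v0 Directed migration speed (um/h).
#' @param D_c Diffusion coefficient of random cluster motion (um^2/h).
#' @param S Attractant secretion rate per cell (arbitrary units/h).
#' @param D Attractant diffusion coefficient (um^2/h). Only the ratio `S/D`
#'   scales the field; direction is unaffected.
#' @param T_d_true Cell doubling time in days; `0` disables growth.
#' @param r_cell Radius of a single cell (um). A cluster of `n` cells has
#'   radius `r_cell * n^(1/3)` (volume conservation).
#' @param dt Integration time step (h). Must be small enough that the
#'   displacement per step stays below `r_cell`, otherwise contacts can be
#'   stepped over; a warning is raised when the configured motility violates
#'   this.
#' @param duration Assay length (days).
#' @param frame_interval Interval between recorded frames (days). Default 1,
#'   mirroring daily imaging of week-long assays.
#' @param response Directed-mode response rule: `"constant"` moves at `v0`
#'   along the gradient direction regardless of its magnitude;
#'   `"proportional"` moves by `chemo_gain * |grad c| * dt`, capped at
#'   `v0 * dt`.
#' @param chemo_gain Mobility coefficient for `response = "proportional"`
#'   (um/h per unit concentration gradient).
#' @param seed Integer seed; all randomness of an assay flows from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(density = 31, mode = "directed", duration = 14, seed = 1)
#' cfg$density
#' @export
sim_config <- function(box_edge = 1000,
                       density = 30,
                       mode = c("directed", "random"),
                       v0 = 2,
                       D_c = 1000,
                       S = 1,
                       D = 100,
                       T_d_true = 0,
                       r_cell = 10,
                       dt = 0.5,
                       duration = 21,
                       frame_interval = 1,
                       response = c("constant", "proportional"),
                       chemo_gain = 1e6,
                       seed = 1L) {
  mode <- match.arg(mode)
  response <- match.arg(response)
  cfg <- list(
    box_edge = box_edge, density = density, mode = mode, v0 = v0,
    D_c = D_c, S = S, D = D, T_d_true = T_d_true, r_cell = r_cell,
    dt = dt, duration = duration, frame_interval = frame_interval,
    response = response, chemo_gain = chemo_gain, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$box_edge > 0, cfg$density >= 0, cfg$dt > 0, cfg$duration > 0,
    cfg$v0 >= 0, cfg$D_c >= 0, cfg$S >= 0, cfg$D > 0, cfg$r_cell > 0,
    cfg$T_d_true >= 0, cfg$frame_interval > 0
  )
  step_disp <- if (cfg$mode == "random") {
    sqrt(2 * cfg$D_c * cfg$dt)
  } else {
    cfg$v0 * cfg$dt
  }
  if (step_disp > cfg$r_cell) {
    warn(sprintf(
      paste0("displacement per step (%.1f um) exceeds r_cell (%.1f um); ",
             "contacts may be stepped over -- reduce dt"),
      step_disp, cfg$r_cell
    ))
  }
  invisible(cfg)
}

#' Rendering configuration for synthetic microscopy z-stacks
#'
#' Parameters of the renderer that turns a simulated cluster state into a
#' microscopy-like grayscale z-stack: each cluster is drawn as a bright ball
#' whose edge blurs and whose intensity attenuates with defocus distance,
#' with optional thin protrusion spicules and additive Gaussian noise.
#'
#' @param pixel_size Lateral pixel size (um/px).
#' @param z_step Axial spacing between planes (um). Stacks of 1 mm gels are
#'   typically acquired every 50 um.
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity
#'   units; foreground amplitude is 1).
#' @param psf_sd Blur growth per unit defocus (um of edge blur per um of
#'   distance from the in-focus plane).
#' @param protrusion_count Number of spicules drawn per cluster (0 disables).
#' @param protrusion_length,protrusion_width Spicule length and width (um).
#' @param protrusion_orientation `"toward_nearest"` points spicules at the
#'   nearest neighbouring cluster; `"random"` orients them uniformly.
#'
#' @return An object of class `render_config`.
#' @export
render_config <- function(pixel_size = 4,
                          z_step = 50,
                          noise_sd = 0,
                          psf_sd = 0.2,
                          protrusion_count = 0,
                          protrusion_length = 60,
                          protrusion_width = 8,
                          protrusion_orientation = c("toward_nearest", "random")) {
  protrusion_orientation <- match.arg(protrusion_orientation)
  stopifnot(pixel_size > 0, z_step > 0, noise_sd >= 0, psf_sd >= 0,
            protrusion_count >= 0, protrusion_length >= 0,
            protrusion_width > 0)
  structure(
    list(pixel_size = pixel_size, z_step = z_step, noise_sd = noise_sd,
         psf_sd = psf_sd, protrusion_count = protrusion_count,
         protrusion_length = protrusion_length,
         protrusion_width = protrusion_width,
         protrusion_orientation = protrusion_orientation),
    class = "render_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$mode, "mode |", x$density, "cells/mm^3 |",
      x$duration, "d |", "box", x$box_edge, "um | seed", x$seed, "\n")
  invisible(x)
}

#' @export
print.render_config <- function(x, ...) {
  cat("<render_config>", x$pixel_size, "um/px | z-step", x$z_step,
      "um | noise sd", x$noise_sd, "\n")
  invisible(x)
}
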