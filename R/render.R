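#' Render a cluster state as a microscopy-like z-stack
#'
#' Draws every cluster as a bright ball on each focal plane: the ball's
#' silhouette (radius `r_i`) is rasterised with a soft Gaussian edge whose
#' width grows with defocus distance (`psf_sd` um of blur per um of
#' distance from the cluster's own plane) and whose amplitude attenuates
#' with defocus, so each object is sharpest and brightest in its in-focus
#' plane. Optional protrusion spicules are drawn as thin rods in the
#' in-focus plane, oriented toward the nearest neighbouring cluster or at
#' random. Additive Gaussian noise completes the model. Rendering is
#' deterministic for a fixed `seed`.
#'
#' @param state A `cluster_state`.
#' @param rc A [render_config()].
#' @param seed Integer seed for noise and random spicule orientation.
#' @return An [image_stack()] covering the assay volume.
#' @export
render_stack <- function(state, rc, seed = 1L) {
  stopifnot(inherits(rc, "render_config"))
  set.seed(as.integer(seed))
  box <- state$box_edge
  npx <- max(1L, round(box / rc$pixel_size))
  z_planes <- seq(0, box, by = rc$z_step)
  nz <- length(z_planes)
  vox <- array(0, dim = c(npx, npx, nz))
  # pixel centers in um (row = y, col = x)
  px_centers <- (seq_len(npx) - 0.5) * rc$pixel_size
  cl <- state$clusters
  sigma0 <- rc$pixel_size / 2
  for (i in seq_len(nrow(cl))) {
    r <- cl$radius[i]
    xc <- cl$x[i]; yc <- cl$y[i]; zc <- cl$z[i]
    for (k in seq_len(nz)) {
      dz <- abs(z_planes[k] - zc)
      sigma <- max(sigma0, rc$psf_sd * dz)
      amp <- r^2 / (r^2 + (rc$psf_sd * dz)^2)
      reach <- r + 4 * sigma
      rows <- which(abs(px_centers - yc) <= reach)
      cols <- which(abs(px_centers - xc) <= reach)
      if (!length(rows) || !length(cols)) next
      d <- sqrt(outer((px_centers[rows] - yc)^2,
                      (px_centers[cols] - xc)^2, "+"))
      vox[rows, cols, k] <- vox[rows, cols, k] +
        amp * pnorm((r - d) / sigma)
    }
    if (rc$protrusion_count > 0) {
      k0 <- which.min(abs(z_planes - zc))
      vox[, , k0] <- draw_spicules(vox[, , k0], cl, i, rc, px_centers)
    }
  }
  if (rc$noise_sd > 0) {
    vox <- vox + array(rnorm(length(vox), 0, rc$noise_sd), dim = dim(vox))
  }
  image_stack(vox, pixel_size = rc$pixel_size, z_step = rc$z_step)
}

# draw protrusion spicules of cluster i onto one plane
draw_spicules <- function(plane, cl, i, rc, px_centers) {
  xc <- cl$x[i]; yc <- cl$y[i]; r <- cl$radius[i]
  k <- rc$protrusion_count
  if (rc$protrusion_orientation == "toward_nearest" && nrow(cl) > 1) {
    others <- cl[-i, , drop = FALSE]
    d2 <- (others$x - xc)^2 + (others$y - yc)^2
    j <- which.min(d2)
    base <- atan2(others$y[j] - yc, others$x[j] - xc)
    angles <- base + (seq_len(k) - 1) * 2 * pi / k
  } else {
    angles <- runif(k, 0, 2 * pi)
  }
  half_w <- rc$protrusion_width / 2
  for (a in angles) {
    u <- c(cos(a), sin(a))
    p0 <- c(xc, yc) + r * u
    p1 <- p0 + rc$protrusion_length * u
    reach <- half_w + rc$pixel_size
    lo <- pmin(p0, p1) - reach; hi <- pmax(p0, p1) + reach
    cols <- which(px_centers >= lo[1] & px_centers <= hi[1])
    rows <- which(px_centers >= lo[2] & px_centers <= hi[2])
    if (!length(rows) || !length(cols)) next
    gx <- matrix(px_centers[cols], length(rows), length(cols), byrow = TRUE)
    gy <- matrix(px_centers[rows], length(rows), length(cols))
    v <- p1 - p0
    tt <- pmin(pmax(((gx - p0[1]) * v[1] + (gy - p0[2]) * v[2]) /
                      sum(v^2), 0), 1)
    dseg <- sqrt((gx - (p0[1] + tt * v[1]))^2 + (gy - (p0[2] + tt * v[2]))^2)
    hit <- dseg <= half_w
    sub <- plane[rows, cols]
    sub[hit] <- pmax(sub[hit], 0.7)
    plane[rows, cols] <- sub
  }
  plane
}
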