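signed_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# evaluate the cross-correlation surface of F = fft(a0) * Conj(fft(b0)) at
# real-valued shifts (sy, sx) of b relative to a
cc_at_shifts <- function(F, sy, sx) {
  ny <- nrow(F); nx <- ncol(F)
  ky <- signed_freqs(ny); kx <- signed_freqs(nx)
  Ey <- exp(-2i * pi * outer(sy, ky) / ny)
  Ex <- exp(-2i * pi * outer(sx, kx) / nx)
  Re(Ey %*% F %*% t(Ex)) / (ny * nx)
}

#' Register two frames by cross-correlation
#'
#' Estimates the translation of `frame_b` relative to `frame_a` (stage
#' offset / gel drift correction) as the shift maximising the zero-mean
#' cross-correlation, computed via FFT for integer shifts and refined to
#' 0.1 px by evaluating the correlation surface on a 10x upsampled local
#' grid around the integer peak. Shifting `frame_b` back by the returned
#' offset maximises its overlap with `frame_a`.
#'
#' @param frame_a,frame_b [projected_image()]s (or plain matrices) of equal
#'   shape.
#' @param upsample Subpixel refinement factor; default 10 (0.1 px grid).
#' @return Named numeric `c(dy, dx)`: row/column displacement of `frame_b`
#'   relative to `frame_a`, in pixels.
#' @export
align_frames <- function(frame_a, frame_b, upsample = 10) {
  a <- if (inherits(frame_a, "projected_image")) frame_a$pixels else frame_a
  b <- if (inherits(frame_b, "projected_image")) frame_b$pixels else frame_b
  if (!all(dim(a) == dim(b))) abort("frames must have identical shapes")
  if (sd(a) == 0 || sd(b) == 0) {
    warn("blank frame: returning zero offset")
    return(c(dy = 0, dx = 0))
  }
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  F <- fft(a0) * Conj(fft(b0))
  cc <- Re(fft(F, inverse = TRUE))
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  ny <- nrow(a); nx <- ncol(a)
  # peak at index u corresponds to shift -u (circular, signed)
  uy <- peak[1] - 1; if (uy > ny / 2) uy <- uy - ny
  ux <- peak[2] - 1; if (ux > nx / 2) ux <- ux - nx
  dy0 <- -uy; dx0 <- -ux
  if (upsample <= 1) return(c(dy = dy0, dx = dx0))
  step <- 1 / upsample
  sy <- dy0 + seq(-1 + step, 1 - step, by = step)
  sx <- dx0 + seq(-1 + step, 1 - step, by = step)
  M <- cc_at_shifts(F, sy, sx)
  best <- which(M == max(M), arr.ind = TRUE)[1, ]
  c(dy = sy[best[1]], dx = sx[best[2]])
}

#' Area velocity from two segmented masks
#'
#' Movement measure insensitive to slow growth: the area of the set-symmetric
#' difference (XOR) of the two aligned foreground masks, converted to um^2
#' and divided by the time lag. Frames a few hours apart (default 3 h)
#' capture relatively fast protrusive movements while overall growth changes
#' the foreground too slowly to register. The alternative
#' `method = "abs_diff"` returns the absolute total-area change instead.
#'
#' @param mask_a,mask_b [class_mask()]s on the same (aligned) pixel grid.
#' @param lag Time between the frames (h); default 3.
#' @param method `"xor"` (default, symmetric difference) or `"abs_diff"`
#'   (absolute difference of total areas).
#' @return Area velocity (um^2/h).
#' @export
area_velocity <- function(mask_a, mask_b, lag = 3,
                          method = c("xor", "abs_diff")) {
  method <- match.arg(method)
  stopifnot(inherits(mask_a, "class_mask"), inherits(mask_b, "class_mask"),
            lag > 0)
  if (!all(dim(mask_a$labels) == dim(mask_b$labels))) {
    abort("masks must have identical shapes")
  }
  if (mask_a$pixel_size != mask_b$pixel_size) {
    abort("masks must share a pixel size")
  }
  ps2 <- mask_a$pixel_size^2
  fa <- mask_a$labels > 0L
  fb <- mask_b$labels > 0L
  area <- switch(method,
                 xor = sum(xor(fa, fb)) * ps2,
                 abs_diff = abs(sum(fa) - sum(fb)) * ps2)
  area / lag
}
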