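#' Grayscale image stack
#'
#' A z-stack of grayscale planes with physical pixel size and z spacing.
#' Voxels are stored as a numeric array indexed `[y, x, z]` (y-down,
#' matching image conventions).
#'
#' @param voxels 3D numeric array `[y, x, z]`, or a 2D matrix for a
#'   single-plane stack.
#' @param pixel_size Lateral pixel size (um/px).
#' @param z_step Axial plane spacing (um).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size, z_step) {
  if (length(dim(voxels)) == 2) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 3, pixel_size > 0, z_step > 0)
  structure(list(voxels = voxels, pixel_size = pixel_size, z_step = z_step),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<image_stack>", d[1], "x", d[2], "px x", d[3], "planes |",
      x$pixel_size, "um/px | z-step", x$z_step, "um\n")
  invisible(x)
}

#' Projected 2D grayscale image
#'
#' @param pixels 2D numeric matrix (y-down).
#' @param pixel_size Pixel size (um/px).
#' @return An object of class `projected_image`.
#' @export
projected_image <- function(pixels, pixel_size) {
  stopifnot(is.matrix(pixels), pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "projected_image")
}

#' @export
print.projected_image <- function(x, ...) {
  cat("<projected_image>", nrow(x$pixels), "x", ncol(x$pixels), "px |",
      x$pixel_size, "um/px\n")
  invisible(x)
}

#' Class mask over background / bulk / protrusion
#'
#' A 2D label image with classes background (0), bulk (1) and
#' protrusion (2) at a known pixel size.
#'
#' @param labels Integer matrix with values in \{0, 1, 2\}.
#' @param pixel_size Pixel size (um/px).
#' @return An object of class `class_mask`.
#' @export
class_mask <- function(labels, pixel_size) {
  stopifnot(is.matrix(labels), pixel_size > 0)
  if (!all(labels %in% c(0L, 1L, 2L))) {
    abort("mask labels must be in {0 = background, 1 = bulk, 2 = protrusion}")
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "class_mask")
}

#' @export
print.class_mask <- function(x, ...) {
  cat("<class_mask>", nrow(x$labels), "x", ncol(x$labels), "px |",
      x$pixel_size, "um/px | bulk", sum(x$labels == 1L),
      "px, protrusion", sum(x$labels == 2L), "px\n")
  invisible(x)
}

# local variance of a plane in a k x k window (replicated boundary)
local_variance <- function(plane, k) {
  kern <- matrix(1 / (k * k), k, k)
  mu <- EBImage::filter2(plane, kern, boundary = "replicate")
  mu2 <- EBImage::filter2(plane^2, kern, boundary = "replicate")
  pmax(mu2 - mu^2, 0)
}

#' Extended-depth-of-field projection by local-variance maximisation
#'
#' Projects a z-stack onto a single image: each output pixel is taken from
#' the plane that maximises the local image variance in a square window of
#' the given physical width (in-focus structures are high-variance). Ties
#' are broken toward the lowest z. The kernel width is converted to the
#' nearest odd pixel count.
#'
#' @param stack An [image_stack()].
#' @param kernel_width Physical width of the variance window (um);
#'   default 8.
#' @return A [projected_image()].
#' @export
edf_project <- function(stack, kernel_width = 8) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (d[3] == 1L) {
    return(projected_image(stack$voxels[, , 1], stack$pixel_size))
  }
  k <- max(1L, round(kernel_width / stack$pixel_size))
  if (k %% 2 == 0) k <- k + 1L
  npix <- d[1] * d[2]
  vmat <- matrix(0, npix, d[3])
  for (z in seq_len(d[3])) {
    vmat[, z] <- as.vector(local_variance(stack$voxels[, , z], k))
  }
  best <- max.col(vmat, ties.method = "first")
  flat <- matrix(stack$voxels, npix, d[3])
  out <- matrix(flat[cbind(seq_len(npix), best)], d[1], d[2])
  projected_image(out, stack$pixel_size)
}

# 8-connected labelling: EBImage::bwlabel (4-connected) + union of
# diagonally adjacent labels
label_components8 <- function(fg) {
  lab <- EBImage::bwlabel(fg * 1)
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]      # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]     # down-left diagonal
  pick <- function(a, b) {
    s <- a > 0 & b > 0 & a != b
    cbind(a[s], b[s])
  }
  pairs <- unique(rbind(pick(a1, b1), pick(a2, b2)))
  if (nrow(pairs)) {
    parent <- seq_len(nlab)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (p in seq_len(nrow(pairs))) {
      ra <- find(pairs[p, 1]); rb <- find(pairs[p, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(nlab), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

#' Segment a projected image into background, bulk and protrusion
#'
#' Deterministic three-class segmentation: foreground is everything above an
#' intensity threshold (Otsu's method by default); bulk is the morphological
#' opening of the foreground with a disk of the given physical radius, which
#' erases structures thinner than the disk; protrusions are the removed
#' foreground pixels restricted to 8-connected residual components that
#' touch bulk and extend more than one pixel beyond it (residuals lying
#' entirely within one pixel of bulk are rasterisation roughness of the bulk
#' boundary and are reassigned to bulk). Thin free-floating debris not
#' attached to any bulk object is left as background.
#'
#' @param image A [projected_image()].
#' @param intensity_threshold `"auto"` (Otsu) or a numeric threshold in
#'   image intensity units; foreground is strictly above it.
#' @param opening_radius Disk radius of the opening (um); default 15, sized
#'   so multi-cell bulk survives while single-cell-wide protrusions
#'   (about 5-20 um across) are removed.
#' @return A [class_mask()].
#' @export
segment_classes <- function(image, intensity_threshold = "auto",
                            opening_radius = 15) {
  stopifnot(inherits(image, "projected_image"))
  px <- image$pixels
  rng <- range(px)
  if (identical(intensity_threshold, "auto")) {
    if (diff(rng) == 0) {
      return(class_mask(matrix(0L, nrow(px), ncol(px)), image$pixel_size))
    }
    norm <- (px - rng[1]) / diff(rng)
    thr_norm <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    thr <- rng[1] + thr_norm * diff(rng)
  } else {
    thr <- intensity_threshold
  }
  fg <- px > thr
  rpx <- max(1L, round(opening_radius / image$pixel_size))
  brush <- EBImage::makeBrush(2L * rpx + 1L, shape = "disc")
  bulk <- EBImage::opening(fg * 1, brush) > 0
  resid <- fg & !bulk
  labels <- matrix(0L, nrow(px), ncol(px))
  labels[bulk] <- 1L
  if (any(resid)) {
    rlab <- label_components8(resid)
    bulk_dil <- EBImage::dilate(bulk * 1, EBImage::makeBrush(3L, "box")) > 0
    touching <- unique(rlab[rlab > 0 & bulk_dil])
    # components fully inside the 1-px bulk halo are boundary roughness
    beyond <- unique(rlab[rlab > 0 & !bulk_dil])
    rim <- setdiff(touching, beyond)
    prot <- setdiff(touching, rim)
    rl <- as.vector(rlab)
    labels[resid & matrix(rl %in% prot, nrow(px))] <- 2L
    labels[resid & matrix(rl %in% rim, nrow(px))] <- 1L
  }
  class_mask(labels, image$pixel_size)
}

#' Remove small isolated objects from a class mask
#'
#' Drops 8-connected foreground components (bulk plus protrusion) whose
#' area-equivalent radius `sqrt(area / pi)` is below the cutoff; components
#' at or above the cutoff are kept (boundary inclusive).
#'
#' @param mask A [class_mask()].
#' @param min_radius Equivalent-radius cutoff (um); default 50.
#' @return The filtered [class_mask()].
#' @export
filter_small <- function(mask, min_radius = 50) {
  stopifnot(inherits(mask, "class_mask"))
  fg <- mask$labels > 0L
  if (!any(fg)) return(mask)
  lab <- label_components8(fg)
  areas <- tabulate(lab[lab > 0])
  eq_r <- sqrt(areas * mask$pixel_size^2 / pi)
  drop <- which(eq_r < min_radius)
  out <- mask$labels
  out[lab %in% drop] <- 0L
  class_mask(out, mask$pixel_size)
}

#' Count independent objects in a class mask
#'
#' Number of 8-connected foreground (bulk plus protrusion) components.
#'
#' @param mask A [class_mask()].
#' @return Integer count.
#' @export
count_objects <- function(mask) {
  stopifnot(inherits(mask, "class_mask"))
  max(label_components8(mask$labels > 0L))
}

#' Per-object measurements of a class mask
#'
#' @param mask A [class_mask()].
#' @return A tibble with one row per 8-connected foreground object:
#'   `id`, `area_um2`, `equiv_radius_um` (`sqrt(area / pi)`) and the
#'   pixel-coordinate centroid (`centroid_y`, `centroid_x`, 0-based).
#' @export
object_table <- function(mask) {
  stopifnot(inherits(mask, "class_mask"))
  lab <- label_components8(mask$labels > 0L)
  nlab <- max(lab)
  if (nlab == 0) {
    return(tibble(id = integer(), area_um2 = numeric(),
                  equiv_radius_um = numeric(), centroid_y = numeric(),
                  centroid_x = numeric()))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  areas_px <- tabulate(ids, nlab)
  tibble(
    id = seq_len(nlab),
    area_um2 = areas_px * mask$pixel_size^2,
    equiv_radius_um = sqrt(areas_px * mask$pixel_size^2 / pi),
    centroid_y = as.numeric(tapply(idx[, 1] - 1, ids, mean)[as.character(seq_len(nlab))]),
    centroid_x = as.numeric(tapply(idx[, 2] - 1, ids, mean)[as.character(seq_len(nlab))])
  )
}

#' Total cluster-occupied area of a mask
#'
#' Bulk plus protrusion pixel count converted to um^2.
#'
#' @param mask A [class_mask()].
#' @return Area (um^2).
#' @export
total_area <- function(mask) {
  stopifnot(inherits(mask, "class_mask"))
  sum(mask$labels > 0L) * mask$pixel_size^2
}

#' Protrusive area ratio relative to a reference area
#'
#' Protrusion-class area of a mask divided by a reference area, conventionally
#' the total cluster-occupied (bulk plus protrusion) area of the first frame
#' of the series. The ratio tracks how protrusive a field becomes relative
#' to its starting footprint.
#'
#' @param mask A [class_mask()] at time t.
#' @param reference_area Total cluster-occupied area of frame 1 (um^2).
#' @return A non-negative fraction.
#' @export
protrusive_ratio <- function(mask, reference_area) {
  stopifnot(inherits(mask, "class_mask"))
  if (!is.numeric(reference_area) || reference_area <= 0) {
    abort("reference_area must be positive (total cluster area of frame 1)")
  }
  sum(mask$labels == 2L) * mask$pixel_size^2 / reference_area
}
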