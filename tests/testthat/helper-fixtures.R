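# shared fixtures and independent oracles, all generated in code

# binary matrix with filled disks at (cy, cx) pixel centres
disk_image <- function(nrow, ncol, cy, cx, r_px, value = 1) {
  m <- matrix(0, nrow, ncol)
  yy <- matrix(seq_len(nrow), nrow, ncol)
  xx <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  for (i in seq_along(cy)) {
    m[(yy - cy[i])^2 + (xx - cx[i])^2 <= r_px[i]^2] <- value
  }
  m
}

# independent 8-connected component count: iterative flood fill
flood_fill_count <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  for (start in which(fg & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    stack <- start
    seen[start] <- TRUE
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      y <- ((p - 1) %% nr) + 1
      x <- ((p - 1) %/% nr) + 1
      for (k in seq_len(nrow(offs))) {
        y2 <- y + offs$dy[k]; x2 <- x + offs$dx[k]
        if (y2 >= 1 && y2 <= nr && x2 >= 1 && x2 <= nc) {
          q <- (x2 - 1) * nr + y2
          if (fg[q] && !seen[q]) {
            seen[q] <- TRUE
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  count
}

# per-component pixel areas via flood fill (same connectivity)
flood_fill_areas <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  seen <- matrix(FALSE, nr, nc)
  areas <- integer(0)
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  for (start in which(fg & !seen)) {
    if (seen[start]) next
    a <- 0L
    stack <- start
    seen[start] <- TRUE
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      a <- a + 1L
      y <- ((p - 1) %% nr) + 1
      x <- ((p - 1) %/% nr) + 1
      for (k in seq_len(nrow(offs))) {
        y2 <- y + offs$dy[k]; x2 <- x + offs$dx[k]
        if (y2 >= 1 && y2 <= nr && x2 >= 1 && x2 <= nc) {
          q <- (x2 - 1) * nr + y2
          if (fg[q] && !seen[q]) {
            seen[q] <- TRUE
            stack <- c(stack, q)
          }
        }
      }
    }
    areas <- c(areas, a)
  }
  areas
}

# decreasing logistic n(t) = b + (n0 - b) / (1 + exp((t - tm)/s))
logistic_counts <- function(t, n0, b, tm, s) {
  b + (n0 - b) / (1 + exp((t - tm) / s))
}

# circularly shift a matrix: result[y, x] = m[y - dy, x - dx]
shift_matrix <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
}

# minimal assay_truth for definition-level tests
fake_truth <- function(initial_count, aggregating_ids) {
  structure(list(initial_count = initial_count,
                 aggregating_ids = aggregating_ids),
            class = "assay_truth")
}
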