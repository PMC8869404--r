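default_fd_box_sizes <- function(mask) {
  lim <- max(2L, floor(min(dim(mask)) / 2))
  sizes <- 2L^(1:12)
  sizes <- sizes[sizes <= lim]
  if (length(sizes) < 4L) sizes <- unique(pmax(2L, round(seq(2, lim, length.out = 4))))
  sizes
}

#' Box-counting fractal dimension of a binary mask
#'
#' Counts the number of `r x r` grid boxes containing foreground for a
#' ladder of box sizes and several grid offsets, and returns the slope
#' of the least-squares fit of `log(N)` against `log(1/r)`. At each size
#' the minimal cover over the tried grid offsets is used (the box count
#' is defined as the smallest number of boxes covering the set; a fixed
#' grid origin systematically overcounts). A plane-filling mask approaches
#' 2, a smooth curve 1; ramified microglia typically fall in between.
#'
#' @param mask binary matrix or [cell_mask()].
#' @param box_sizes integer vector (>= 4 sizes spanning at least one
#'   decade recommended); defaults to powers of two up to half the
#'   image side.
#' @param n_offsets number of diagonal grid offsets averaged per size.
#' @return dimensionless estimate of the box-counting dimension.
#' @export
box_count_fractal_dimension <- function(mask, box_sizes = NULL, n_offsets = 4L) {
  m <- as_binary_matrix(mask)
  gp_assert(any(m), "cannot estimate fractal dimension of an empty mask",
            "gp_empty_mask_error")
  if (is.null(box_sizes)) box_sizes <- default_fd_box_sizes(m)
  box_sizes <- sort(unique(as.integer(box_sizes)))
  gp_assert(length(box_sizes) >= 2L && all(box_sizes >= 1L),
            "need at least two positive box sizes")
  idx <- which(m, arr.ind = TRUE)
  counts <- vapply(box_sizes, function(r) {
    offs <- unique(round(seq(0L, r - 1L, length.out = max(1L, n_offsets))))
    min(vapply(offs, function(o) {
      bx <- (idx[, 1] + o - 1L) %/% r
      by <- (idx[, 2] + o - 1L) %/% r
      length(unique(bx * (max(by) + 2L) + by))
    }, numeric(1)))
  }, numeric(1))
  fit <- lm(log(counts) ~ log(1 / box_sizes))
  unname(coef(fit)[2])
}

default_lac_box_sizes <- function(mask) {
  sizes <- 2L^(1:12)
  sizes <- sizes[sizes <= floor(min(dim(mask)) / 2)]
  if (length(sizes) == 0L) sizes <- 1L
  sizes
}

#' Sliding-box lacunarity of a binary mask
#'
#' For each box size `r`, slides an `r x r` window over every position
#' (stride 1) and computes the squared coefficient of variation
#' `(sigma/mu)^2` of the foreground mass across positions; the reported
#' lacunarity is the mean over sizes. The window domain is the
#' foreground bounding box, so the measure describes the cell's own
#' texture rather than how much empty canvas surrounds it. Gappy,
#' heterogeneous masks (e.g. ramified cells) score high; homogeneous
#' masks score near 0.
#'
#' @inheritParams box_count_fractal_dimension
#' @param box_sizes window sizes, each smaller than the image sides.
#' @return dimensionless mean lacunarity; also carries the per-size
#'   values as attribute `"per_size"`.
#' @export
sliding_box_lacunarity <- function(mask, box_sizes = NULL) {
  m <- as_binary_matrix(mask)
  gp_assert(any(m), "cannot compute lacunarity of an empty mask",
            "gp_empty_mask_error")
  idx <- which(m, arr.ind = TRUE)
  m <- m[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]), drop = FALSE]
  if (is.null(box_sizes)) box_sizes <- default_lac_box_sizes(m)
  box_sizes <- sort(unique(as.integer(box_sizes)))
  gp_assert(all(box_sizes >= 1L & box_sizes <= min(dim(m))),
            "box sizes must be positive and no larger than the image")
  # summed-area table for O(1) window sums
  sat <- apply(apply(m * 1L, 2, cumsum), 1, cumsum)
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  window_sums <- function(r) {
    nr <- nrow(m) - r + 1L; nc <- ncol(m) - r + 1L
    i <- seq_len(nr); j <- seq_len(nc)
    sat[i + r, j + r, drop = FALSE] - sat[i, j + r, drop = FALSE] -
      sat[i + r, j, drop = FALSE] + sat[i, j, drop = FALSE]
  }
  per_size <- vapply(box_sizes, function(r) {
    w <- window_sums(r)
    mu <- mean(w)
    if (mu == 0) return(0)
    s2 <- mean((w - mu)^2) # population variance over all positions
    s2 / mu^2
  }, numeric(1))
  structure(mean(per_size), per_size = setNames(per_size, box_sizes))
}
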