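# --- outer boundary tracing and perimeter estimation -----------------------

# Moore-neighbour tracing of the outer boundary of the (single) foreground
# component. Returns an n x 2 matrix of pixel coordinates (row, col) forming
# a closed contour (first pixel not repeated).
trace_outer_contour <- function(mask) {
  m <- as_binary_matrix(mask)
  gp_assert(any(m), "cannot trace an empty mask", "gp_empty_mask_error")
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 1L) return(idx)
  # start: topmost pixel of the leftmost occupied column (its West
  # neighbour is guaranteed background)
  start <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE][1, ]
  nr <- nrow(m); ncl <- ncol(m)
  fg <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= ncl && m[p[1], p[2]]
  # Moore neighbourhood, clockwise starting West (rows grow downward)
  moore <- cbind(
    dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
    dc = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  )
  dir_index <- function(d) which(moore[, 1] == d[1] & moore[, 2] == d[2])

  max_steps <- 4L * nrow(idx) + 8L
  contour <- matrix(0L, nrow = max_steps, ncol = 2L)
  contour[1, ] <- start
  n_out <- 1L
  cur <- start
  d <- 1L # direction (index into moore) from cur to its backtrack pixel
  # stop when a directed state (pixel, backtrack direction) repeats:
  # the trace has completed its cycle around the boundary
  seen <- new.env(hash = TRUE, parent = emptyenv())
  state_key <- function(p, d) paste(p[1], p[2], d)
  assign(state_key(cur, d), TRUE, envir = seen)
  for (step in seq_len(max_steps)) {
    moved <- FALSE
    for (k in 1:8) {
      j <- ((d - 1L + k) %% 8L) + 1L
      probe <- c(cur[1] + moore[j, 1], cur[2] + moore[j, 2])
      if (fg(probe)) {
        jprev <- ((d - 1L + k - 1L) %% 8L) + 1L
        bpix <- c(cur[1] + moore[jprev, 1], cur[2] + moore[jprev, 2])
        cur <- probe
        d <- dir_index(c(bpix[1] - cur[1], bpix[2] - cur[2]))
        moved <- TRUE
        break
      }
    }
    if (!moved) break # isolated start pixel
    key <- state_key(cur, d)
    if (!is.null(seen[[key]])) break
    assign(key, TRUE, envir = seen)
    n_out <- n_out + 1L
    if (n_out > max_steps) break
    contour[n_out, ] <- cur
  }
  n_out <- min(n_out, max_steps)
  contour[seq_len(n_out), , drop = FALSE]
}

# Perimeter of the traced outer boundary, in pixels.
# "chain": Vossepoel-Smeulders corrected chain code (default; near-unbiased
#   for smooth outlines), "chain_raw": 1/sqrt(2) step metric,
# "crofton": 4-direction Cauchy-Crofton intercept estimate.
perimeter_px <- function(mask, method = c("chain", "chain_raw", "crofton")) {
  method <- match.arg(method)
  m <- as_binary_matrix(mask)
  if (method == "crofton") {
    trans <- function(a) sum(abs(diff(a)))
    n_h <- sum(apply(cbind(0L, m * 1L, 0L), 1, trans))
    n_v <- sum(apply(rbind(0L, m * 1L, 0L), 2, trans))
    diag_trans <- function(mm) {
      nr <- nrow(mm); nc <- ncol(mm)
      tot <- 0
      for (k in (-(nr - 1L)):(nc - 1L)) {
        d <- mm[row(mm) + k == col(mm)]
        tot <- tot + trans(c(0L, d, 0L))
      }
      tot
    }
    n_d1 <- diag_trans(m * 1L)
    n_d2 <- diag_trans(m[nrow(m):1, , drop = FALSE] * 1L)
    return((pi / 2) * (n_h + n_v + (n_d1 + n_d2) / sqrt(2)) / 4)
  }
  ct <- trace_outer_contour(m)
  if (nrow(ct) < 2L) return(0)
  closed <- rbind(ct, ct[1, ])
  steps <- diff(closed)
  diag_step <- rowSums(abs(steps)) == 2L
  if (method == "chain_raw") {
    return(sum(ifelse(diag_step, sqrt(2), 1)))
  }
  # direction changes (corners) between consecutive chain steps
  dirs <- atan2(steps[, 1], steps[, 2])
  n_corner <- sum(abs(diff(c(dirs, dirs[1]))) > 1e-9)
  0.980 * sum(!diag_step) + 1.406 * sum(diag_step) - 0.091 * n_corner
}

# --- convex hull geometry ---------------------------------------------------

# hull over foreground pixel centres; returns vertices (x = col, y = row)
# in counter-clockwise order
hull_vertices <- function(mask) {
  m <- as_binary_matrix(mask)
  idx <- which(m, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  gp_assert(nrow(pts) >= 3L, "mask has fewer than 3 foreground pixels",
            "gp_degenerate_hull_error")
  h <- grDevices::chull(pts)
  v <- pts[rev(h), , drop = FALSE] # chull is clockwise; reverse to CCW
  if (nrow(v) < 3L || abs(polygon_area(v)) < .Machine$double.eps) {
    gp_stop("foreground pixels are collinear; convex hull is degenerate",
            "gp_degenerate_hull_error")
  }
  v
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

polygon_perimeter <- function(v) {
  d <- diff(rbind(v, v[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

max_span <- function(v) {
  d <- as.matrix(dist(v))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  list(span = max(d), i = ij[1], j = ij[2])
}

# width of the hull perpendicular to a unit direction u
perpendicular_width <- function(v, u) {
  n <- c(-u[2], u[1])
  proj <- v %*% n
  max(proj) - min(proj)
}

# minimum enclosing circle (Welzl's algorithm) of a point set
min_enclosing_circle <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  circ2 <- function(a, b) {
    c0 <- (a + b) / 2
    list(c = c0, r = sqrt(sum((a - c0)^2)))
  }
  circ3 <- function(a, b, c) {
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) {
      # collinear: widest pair
      cands <- list(circ2(a, b), circ2(a, c), circ2(b, c))
      return(cands[[which.max(vapply(cands, `[[`, numeric(1), "r"))]])
    }
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) + sum(c^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) + sum(c^2) * (b[1] - a[1])) / d
    c0 <- c(ux, uy)
    list(c = c0, r = sqrt(sum((a - c0)^2)))
  }
  trivial <- function(R) {
    k <- length(R)
    if (k == 0L) return(list(c = c(0, 0), r = -1))
    if (k == 1L) return(list(c = pts[R[1], ], r = 0))
    if (k == 2L) return(circ2(pts[R[1], ], pts[R[2], ]))
    circ3(pts[R[1], ], pts[R[2], ], pts[R[3], ])
  }
  inside <- function(D, p) D$r >= 0 && sum((p - D$c)^2) <= (D$r * (1 + 1e-10))^2 + 1e-9
  ord <- sample.int(n) # expected linear time; seeded by caller context
  D <- trivial(integer(0))
  for (i in seq_len(n)) {
    p <- pts[ord[i], ]
    if (inside(D, p)) next
    D <- trivial(ord[i])
    for (j in seq_len(i - 1L)) {
      q <- pts[ord[j], ]
      if (inside(D, q)) next
      D <- circ2(p, q)
      for (k in seq_len(j - 1L)) {
        s <- pts[ord[k], ]
        if (inside(D, s)) next
        D <- circ3(p, q, s)
      }
    }
  }
  D
}

# --- the 15 shape features --------------------------------------------------

#' Fifteen shape, size and texture features of a cell mask
#'
#' Computes the hull-, boundary- and texture-based feature block:
#' fractal dimension (box counting), lacunarity (sliding box), density
#' (foreground pixels / hull area, dimensionless, may exceed 1 for
#' convex blobs under the pixel-centre hull convention), span ratio
#' (hull major axis / perpendicular width), convex hull area, perimeter
#' and circularity, bounding-circle diameter (minimum enclosing circle
#' of the hull vertices), mean/max radius and max/min radius ratio of
#' hull vertices about the hull centroid, maximum span across the hull,
#' cell area, traced-boundary cell perimeter, and cell circularity
#' (4 pi area / perimeter^2).
#'
#' @param mask a [cell_mask()] or binary matrix.
#' @param calibration micrometres per pixel (defaults to the mask's).
#' @param perimeter_method see [transformation_index()]; default
#'   corrected chain code.
#' @param fd_box_sizes,lac_box_sizes box-size ladders forwarded to
#'   [box_count_fractal_dimension()] and [sliding_box_lacunarity()].
#' @return named numeric vector of length 15 (see
#'   [shape_feature_names()]).
#' @export
shape_feature_vector <- function(mask, calibration = NULL,
                                 perimeter_method = "chain",
                                 fd_box_sizes = NULL, lac_box_sizes = NULL) {
  calib <- mask_calibration(mask, calibration)
  m <- as_binary_matrix(mask)
  gp_assert(any(m), "empty mask", "gp_empty_mask_error")
  v <- hull_vertices(m)

  hull_area_px <- abs(polygon_area(v))
  hull_perim_px <- polygon_perimeter(v)
  centroid <- polygon_centroid(v)
  radii <- sqrt(rowSums(sweep(v, 2, centroid)^2))
  sp <- max_span(v)
  u <- (v[sp$j, ] - v[sp$i, ]) / sp$span
  minor <- perpendicular_width(v, u)
  circle <- min_enclosing_circle(v)

  n_fg <- sum(m)
  cell_perim_px <- perimeter_px(m, method = perimeter_method)

  fd <- box_count_fractal_dimension(m, box_sizes = fd_box_sizes)
  lac <- sliding_box_lacunarity(m, box_sizes = lac_box_sizes)

  out <- c(
    fractal_dimension = fd,
    lacunarity = lac,
    density = n_fg / hull_area_px,
    span_ratio = sp$span / minor,
    convex_hull_area = hull_area_px * calib^2,
    convex_hull_perimeter = hull_perim_px * calib,
    convex_hull_circularity = 4 * pi * hull_area_px / hull_perim_px^2,
    bounding_circle_diameter = 2 * circle$r * calib,
    mean_radius = mean(radii) * calib,
    max_span_across_hull = sp$span * calib,
    max_min_radii_ratio = max(radii) / min(radii),
    max_radius = max(radii) * calib,
    cell_area = n_fg * calib^2,
    cell_perimeter = cell_perim_px * calib,
    cell_circularity = 4 * pi * n_fg / cell_perim_px^2
  )
  out[shape_feature_names()]
}
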