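#' @keywords internal
"_PACKAGE"

#' @importFrom stats complete.cases cov dist dnorm kmeans lm median p.adjust
#'   pchisq prcomp pt qt quantile rbinom rlnorm rnbinom rnorm runif sd setNames
#'   t.test var fisher.test dhyper coef predict
#' @importFrom utils head read.delim write.table modifyList
NULL

# internal: stop with a classed condition so callers/tests can match on class
`%||%` <- function(a, b) if (is.null(a)) b else a

gp_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "gliaProfiler_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

gp_assert <- function(cond, msg, class = "gp_validation_error") {
  if (!isTRUE(cond)) gp_stop(msg, class)
  invisible(TRUE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# binary matrix coercion: accepts logical or numeric rasters
as_binary_matrix <- function(x) {
  gp_assert(is.matrix(x), "mask must be a matrix")
  if (is.logical(x)) {
    m <- x
    m[is.na(m)] <- FALSE
  } else {
    m <- !is.na(x) & x > 0
  }
  m
}

# pad a logical matrix with `n` rings of FALSE
pad_false <- function(m, n = 1L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr + 2L * n, nc + 2L * n)
  out[(n + 1L):(n + nr), (n + 1L):(n + nc)] <- m
  out
}

# shift a matrix by (dr, dc), filling with FALSE/0
shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighbourhood offsets in clockwise order starting north
NB8 <- cbind(
  dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
  dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
)

# label 8-connected components via union-find; returns integer matrix
# (0 = background)
label_components <- function(mask) {
  mask <- as_binary_matrix(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask)) return(out)
  n <- sum(mask)
  idmap <- matrix(0L, nrow(mask), ncol(mask))
  idmap[mask] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  # scan the 4 backward offsets once; each fg pixel unions with earlier fg
  for (off in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L))) {
    a <- idmap[mask & shift_mat(mask, -off[1], -off[2])]
    b <- shift_mat(idmap, -off[1], -off[2], fill = 0L)[mask & shift_mat(mask, -off[1], -off[2])]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out[mask] <- match(roots, unique(roots))
  out
}

# Otsu threshold of a numeric matrix scaled to [0, 1]
otsu_threshold <- function(x, levels = 256L) {
  h <- tabulate(pmin(levels, 1L + floor(as.vector(x) * (levels - 1L))), nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  (k - 0.5) / (levels - 1L)
}

n_components <- function(mask) {
  max(label_components(mask))
}

# count of background components not touching the border = holes
# (8-connected background; adequate for the rasters used here)
count_holes <- function(mask) {
  mask <- as_binary_matrix(mask)
  bg <- !pad_false(mask, 1L)
  lab <- label_components(bg)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  length(setdiff(unique(lab[lab > 0]), border_labels))
}

# deterministic RNG scoping: all generators funnel through this
with_seed <- function(seed, code) {
  gp_assert(is_scalar_num(seed), "seed must be a single finite number")
  withr::with_seed(as.integer(seed), code)
}
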