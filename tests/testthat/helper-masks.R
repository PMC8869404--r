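# hand-constructed oracle rasters used across the morphometry tests

# horizontal bar: `thick` px tall, `len` px long
make_bar <- function(len = 30L, thick = 3L, pad = 6L) {
  m <- matrix(FALSE, thick + 2L * pad, len + 2L * pad)
  m[pad + seq_len(thick), pad + seq_len(len)] <- TRUE
  m
}

# plus sign: two `arm` px long, 1 px wide strokes crossing at the centre
make_plus <- function(arm = 21L, pad = 5L) {
  n <- arm + 2L * pad
  ctr <- pad + (arm + 1L) %/% 2L
  m <- matrix(FALSE, n, n)
  m[ctr, pad + seq_len(arm)] <- TRUE
  m[pad + seq_len(arm), ctr] <- TRUE
  m
}

# L-shaped 1-px path: two 11-pixel orthogonal arms sharing the corner pixel
make_L <- function(arm = 11L, pad = 5L) {
  n <- arm + 2L * pad
  m <- matrix(FALSE, n, n)
  m[pad + 1L, pad + seq_len(arm)] <- TRUE
  m[pad + seq_len(arm), pad + arm] <- TRUE
  m
}

# filled digital disc of radius r
make_disc <- function(r = 50L, pad = 6L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  outer(seq_len(n), seq_len(n), function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

# Sierpinski carpet raster of given depth (side 3^depth)
make_sierpinski <- function(depth = 4L) {
  side <- 3L^depth
  m <- matrix(TRUE, side, side)
  for (k in seq_len(depth)) {
    s <- 3L^k
    third <- 3L^(k - 1L)
    starts <- seq(1L, side, by = s)
    for (i in starts) for (j in starts) {
      m[i + third + 0:(third - 1L), j + third + 0:(third - 1L)] <- FALSE
    }
  }
  m
}

# rotate a matrix by 90 degrees
rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# brute-force two-sided Fisher p by hypergeometric enumeration
brute_fisher_p <- function(a, b, c_, d) {
  m1 <- a + b
  n <- a + c_
  N <- a + b + c_ + d
  sup <- max(0L, n - (N - m1)):min(n, m1)
  pr <- dhyper(sup, m1, N - m1, n)
  pa <- dhyper(a, m1, N - m1, n)
  sum(pr[pr <= pa * (1 + 1e-7)])
}

# fixture gene-set readers
fixture_set <- function(file) {
  read_gene_set_csv(system.file("extdata", file, package = "gliaProfiler"))
}
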