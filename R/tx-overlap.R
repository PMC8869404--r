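#' Directional gene set
#'
#' A named set of gene symbols with optional per-gene direction labels
#' (`"up"`/`"down"`). Symbols are matched case-insensitively after
#' whitespace stripping; the original capitalisation is preserved for
#' output.
#'
#' @param genes character vector of gene symbols (unique after
#'   normalisation).
#' @param directions optional character vector (`"up"`/`"down"`),
#'   same length as `genes`, or a named vector keyed by gene.
#' @param name set label.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(genes, directions = NULL, name = "set") {
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  key <- tolower(genes)
  gp_assert(!anyDuplicated(key), sprintf("duplicate gene symbols in set '%s'", name))
  if (!is.null(directions)) {
    if (!is.null(names(directions))) {
      directions <- unname(directions[match(key, tolower(trimws(names(directions))))])
    }
    gp_assert(length(directions) == length(genes),
              "directions must align with genes")
    gp_assert(all(directions %in% c("up", "down")),
              "directions must be 'up' or 'down'")
  }
  structure(list(name = name, genes = genes, key = key, directions = directions),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> '%s': %d genes%s\n", x$name, length(x$genes),
              if (is.null(x$directions)) "" else sprintf(
                " (%d up / %d down)", sum(x$directions == "up"),
                sum(x$directions == "down"))))
  invisible(x)
}

as_gene_set <- function(x, name = "set") {
  if (inherits(x, "gene_set")) return(x)
  gene_set(x, name = name)
}

#' Fisher's exact overlap test with Baptista-Pike odds-ratio CI
#'
#' Builds the 2x2 contingency table (in both / A only / B only /
#' neither) of two gene sets over a stated gene universe, computes the
#' exact two-sided Fisher p (hypergeometric point-probability rule),
#' the sample odds ratio `ad/bc` (Haldane 0.5 continuity correction
#' when a cell is zero, flagged), and an exact 95% Baptista-Pike
#' confidence interval for the odds ratio, obtained by inverting the
#' point-probability test of the noncentral hypergeometric likelihood.
#' Zero marginal cells give one-sided intervals with an infinite or
#' zero bound, reported explicitly.
#'
#' @param set_a,set_b [gene_set()]s or character vectors.
#' @param universe_size total number of genes tested (default 23930,
#'   the targeted mouse transcriptome panel: 20767 RefSeq + 3163
#'   XM/XR models).
#' @param conf_level confidence level of the odds-ratio interval.
#' @return list of class `overlap_result`: `table` (2x2), `p`,
#'   `odds_ratio`, `or_haldane` flag, `ci` (lower, upper),
#'   `conf_level`, `universe_size`.
#' @export
fisher_overlap <- function(set_a, set_b, universe_size = 23930,
                           conf_level = 0.95) {
  A <- as_gene_set(set_a, "A"); B <- as_gene_set(set_b, "B")
  a <- sum(A$key %in% B$key)
  b <- length(A$key) - a
  c_ <- length(B$key) - a
  d <- universe_size - a - b - c_
  if (d < 0) {
    gp_stop(sprintf(
      "universe_size (%d) smaller than the union of the two sets (%d)",
      universe_size, a + b + c_), "gp_universe_error")
  }
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(c("in_A", "not_A"), c("in_B", "not_B")))
  p <- fisher.test(tab)$p.value
  haldane <- any(tab == 0)
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  ci <- baptista_pike_ci(a, b, c_, d, conf_level = conf_level)
  structure(
    list(table = tab, p = p, odds_ratio = or, or_haldane = haldane,
         ci = ci, conf_level = conf_level, universe_size = universe_size),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> a=%d b=%d c=%d d=%d (universe %d)\n  Fisher p = %.4g, OR = %.4g [%.4g, %.4g] (%.0f%% Baptista-Pike)\n",
    x$table[1, 1], x$table[1, 2], x$table[2, 1], x$table[2, 2],
    x$universe_size, x$p, x$odds_ratio, x$ci[1], x$ci[2], 100 * x$conf_level
  ))
  invisible(x)
}

# noncentral hypergeometric log-pmf over the support, up to a constant
nchg_logpmf <- function(support, m1, m2, n, log_psi) {
  lchoose(m1, support) + lchoose(m2, n - support) + support * log_psi
}

# point-probability (Baptista-Pike) two-sided p at odds ratio psi
nchg_pointprob_p <- function(a, m1, m2, n, log_psi) {
  support <- max(0L, n - m2):min(n, m1)
  lp <- nchg_logpmf(support, m1, m2, n, log_psi)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  pa <- pr[support == a]
  sum(pr[pr <= pa * (1 + 1e-9)])
}

#' Baptista-Pike exact confidence interval for a 2x2 odds ratio
#'
#' Inverts the point-probability test of the conditional (noncentral
#' hypergeometric) likelihood: the interval is the set of odds-ratio
#' values whose two-sided point-probability p exceeds
#' `1 - conf_level`. Bounds are found by bisection on the log odds
#' ratio. When the observed count sits at an end of its support the
#' corresponding bound is 0 or Inf.
#'
#' @param a,b,c_,d cells of the 2x2 table (a = in both).
#' @param conf_level confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
baptista_pike_ci <- function(a, b, c_, d, conf_level = 0.95) {
  alpha <- 1 - conf_level
  m1 <- a + b; m2 <- c_ + d; n <- a + c_
  lo_sup <- max(0L, n - m2); hi_sup <- min(n, m1)
  if (lo_sup == hi_sup) return(c(0, Inf)) # degenerate support: no information
  pfun <- function(lpsi) nchg_pointprob_p(a, m1, m2, n, lpsi)

  bisect <- function(f, lo, hi, tol = 1e-8) {
    flo <- f(lo)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (sign(fm) == sign(flo)) lo <- mid else hi <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }

  # conditional MLE neighbourhood: psi where p() is maximal; use sample
  # log-OR (Haldane-corrected) as centre
  centre <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)))

  lower <- if (a == lo_sup) 0 else {
    # p(psi) increases from ~0 (psi -> 0) to ~1 near the centre
    f <- function(l) pfun(l) - alpha
    lo <- centre - 40
    if (f(lo) > 0) 0 else exp(bisect(f, lo, centre))
  }
  upper <- if (a == hi_sup) Inf else {
    f <- function(l) alpha - pfun(l) # increases with psi beyond the centre
    hi <- centre + 40
    if (pfun(hi) > alpha) Inf else exp(bisect(f, centre, hi))
  }
  c(lower = unname(lower), upper = unname(upper))
}

#' Direction concordance of two overlapping gene sets
#'
#' Counts, among the genes shared by two direction-annotated sets, how
#' many have the same direction label (concordant) and how many differ
#' (discordant).
#'
#' @param set_a,set_b direction-annotated [gene_set()]s.
#' @return list: `overlap`, `concordant`, `discordant`, and `genes`, a
#'   data.frame with per-gene directions and classification.
#' @export
direction_concordance <- function(set_a, set_b) {
  gp_assert(inherits(set_a, "gene_set") && inherits(set_b, "gene_set"),
            "both arguments must be gene_set objects")
  shared <- intersect(set_a$key, set_b$key)
  if (length(shared) == 0L) {
    return(list(overlap = 0L, concordant = 0L, discordant = 0L,
                genes = data.frame(gene = character(0), dir_a = character(0),
                                   dir_b = character(0), concordant = logical(0))))
  }
  gp_assert(!is.null(set_a$directions) && !is.null(set_b$directions),
            "both sets must carry direction annotations")
  ia <- match(shared, set_a$key); ib <- match(shared, set_b$key)
  da <- set_a$directions[ia]; db <- set_b$directions[ib]
  missing <- shared[is.na(da) | is.na(db)]
  if (length(missing) > 0L) {
    gp_stop(sprintf("shared gene(s) without direction annotation: %s",
                    paste(set_a$genes[match(missing, set_a$key)], collapse = ", ")),
            "gp_missing_direction_error")
  }
  conc <- da == db
  list(
    overlap = length(shared),
    concordant = sum(conc),
    discordant = sum(!conc),
    genes = data.frame(
      gene = set_a$genes[ia], dir_a = da, dir_b = db, concordant = conc,
      stringsAsFactors = FALSE
    )
  )
}
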