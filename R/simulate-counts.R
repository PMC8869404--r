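#' Simulate a bulk RNA count matrix with planted differential expression
#'
#' Gamma-Poisson (negative binomial) counts for two groups with a set
#' of planted up- and down-regulated genes at a fixed log2 effect.
#' Baseline means are drawn log-normal (default meanlog `log(500)`,
#' sdlog 1: the moderate spread typical of a targeted amplicon panel),
#' and the case-group mean of planted genes is scaled by
#' `2^(+-log2_effect)`.
#'
#' @param n_genes number of genes.
#' @param n_ctrl,n_case samples per group (>= 2 each).
#' @param n_up,n_down numbers of planted up-/down-regulated genes
#'   (disjoint, drawn at random from the gene index).
#' @param log2_effect absolute planted effect in log2 units (> 0 when
#'   genes are planted; 0 turns the planted sets into nulls).
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion mu^2`); 0 gives Poisson counts.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline mean.
#' @param planted_up,planted_down optional explicit gene indices for
#'   the planted sets (must be disjoint); when NULL they are drawn at
#'   random and `n_up`/`n_down` give their sizes.
#' @param seed integer seed (the generator is a pure function of the
#'   arguments).
#' @return list with `counts` (integer matrix, genes x samples, gene
#'   rownames, sample colnames), `groups` (factor ctrl/case), and
#'   `truth` (data.frame gene/status with status in
#'   up/down/null).
#' @export
simulate_count_matrix <- function(n_genes = 20000L, n_ctrl = 4L, n_case = 4L,
                                  n_up = 83L, n_down = 18L, log2_effect = 2,
                                  dispersion = 0.05,
                                  baseline_meanlog = log(500),
                                  baseline_sdlog = 1,
                                  planted_up = NULL, planted_down = NULL,
                                  seed = 1L) {
  gp_assert(n_ctrl >= 2L && n_case >= 2L, "each group needs >= 2 samples")
  gp_assert(dispersion >= 0, "dispersion must be >= 0")
  gp_assert(log2_effect >= 0, "log2_effect must be >= 0")
  if (!is.null(planted_up) || !is.null(planted_down)) {
    planted_up <- as.integer(planted_up %||% integer(0))
    planted_down <- as.integer(planted_down %||% integer(0))
    gp_assert(length(intersect(planted_up, planted_down)) == 0L,
              "planted_up and planted_down must be disjoint")
    gp_assert(all(c(planted_up, planted_down) >= 1L) &&
                all(c(planted_up, planted_down) <= n_genes),
              "planted indices out of range")
    n_up <- length(planted_up); n_down <- length(planted_down)
  }
  gp_assert(n_up + n_down <= n_genes,
            "planted gene counts exceed the number of genes")

  genes <- sprintf("gene_%05d", seq_len(n_genes))
  samples <- c(sprintf("ctrl_%d", seq_len(n_ctrl)), sprintf("case_%d", seq_len(n_case)))
  groups <- factor(rep(c("ctrl", "case"), c(n_ctrl, n_case)), levels = c("ctrl", "case"))

  out <- with_seed(seed, {
    if (is.null(planted_up) && is.null(planted_down)) {
      planted <- sample.int(n_genes, n_up + n_down)
      up_idx <- planted[seq_len(n_up)]
      down_idx <- planted[n_up + seq_len(n_down)]
    } else {
      up_idx <- planted_up
      down_idx <- planted_down
    }
    base <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    mu_case <- base
    mu_case[up_idx] <- base[up_idx] * 2^log2_effect
    mu_case[down_idx] <- base[down_idx] * 2^(-log2_effect)
    draw <- function(mu, n) {
      m <- matrix(rep(mu, n), nrow = length(mu))
      if (dispersion > 0) {
        matrix(rnbinom(length(m), mu = m, size = 1 / dispersion), nrow = length(mu))
      } else {
        matrix(stats::rpois(length(m), m), nrow = length(mu))
      }
    }
    counts <- cbind(draw(base, n_ctrl), draw(mu_case, n_case))
    status <- rep("null", n_genes)
    status[up_idx] <- "up"
    status[down_idx] <- "down"
    list(counts = counts, status = status)
  })
  counts <- out$counts
  dimnames(counts) <- list(genes, samples)
  storage.mode(counts) <- "integer"
  list(
    counts = counts,
    groups = groups,
    truth = data.frame(gene = genes, status = out$status, stringsAsFactors = FALSE)
  )
}
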