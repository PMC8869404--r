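#' Simulate two direction-annotated gene sets with a planted overlap
#'
#' Builds two gene sets over a synthetic symbol universe such that they
#' share exactly `planted_overlap` genes, of which exactly
#' `planted_concordant` carry the same direction label in both sets.
#' Emulates the cross-study comparisons in which a disease DEG list is
#' intersected with published microglial signatures.
#'
#' @param universe_size number of genes in the universe.
#' @param size_a,size_b sizes of the two sets.
#' @param planted_overlap number of shared genes
#'   (`<= min(size_a, size_b)`).
#' @param planted_concordant shared genes given equal directions
#'   (`<= planted_overlap`).
#' @param seed integer seed.
#' @return list with `set_a`, `set_b` ([gene_set()]s), `universe`
#'   (character vector) and `truth` (data.frame of shared genes with
#'   their planted concordance).
#' @export
simulate_overlap_gene_sets <- function(universe_size, size_a, size_b,
                                       planted_overlap, planted_concordant,
                                       seed = 1L) {
  gp_assert(planted_concordant <= planted_overlap,
            "planted_concordant must be <= planted_overlap")
  gp_assert(planted_overlap <= min(size_a, size_b),
            "planted_overlap must be <= both set sizes")
  gp_assert(size_a + size_b - planted_overlap <= universe_size,
            "sets do not fit in the universe")
  universe <- sprintf("Gene%05d", seq_len(universe_size))
  out <- with_seed(seed, {
    picks <- sample.int(universe_size, size_a + size_b - planted_overlap)
    shared <- picks[seq_len(planted_overlap)]
    only_a <- picks[planted_overlap + seq_len(size_a - planted_overlap)]
    only_b <- picks[size_a + seq_len(size_b - planted_overlap)]
    dir_a_shared <- sample(c("up", "down"), planted_overlap, replace = TRUE)
    dir_b_shared <- dir_a_shared
    if (planted_overlap > planted_concordant) {
      flip <- (planted_concordant + 1L):planted_overlap
      dir_b_shared[flip] <- ifelse(dir_a_shared[flip] == "up", "down", "up")
    }
    list(
      shared = shared, only_a = only_a, only_b = only_b,
      dir_a = c(dir_a_shared, sample(c("up", "down"), length(only_a), replace = TRUE)),
      dir_b = c(dir_b_shared, sample(c("up", "down"), length(only_b), replace = TRUE))
    )
  })
  set_a <- gene_set(universe[c(out$shared, out$only_a)], out$dir_a, name = "A")
  set_b <- gene_set(universe[c(out$shared, out$only_b)], out$dir_b, name = "B")
  list(
    set_a = set_a, set_b = set_b, universe = universe,
    truth = data.frame(
      gene = universe[out$shared],
      concordant = seq_len(planted_overlap) <= planted_concordant,
      stringsAsFactors = FALSE
    )
  )
}
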