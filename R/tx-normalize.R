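#' Reads-per-million normalisation
#'
#' Scales each sample (column) of a count matrix so that it sums to
#' one million.
#'
#' @param counts numeric matrix, genes in rows, samples in columns
#'   (rownames = gene ids).
#' @return matrix of the same shape; every column sums to 1e6.
#' @export
rpm_normalize <- function(counts) {
  gp_assert(is.matrix(counts) && is.numeric(counts), "counts must be a numeric matrix")
  gp_assert(all(counts >= 0), "counts must be non-negative")
  totals <- colSums(counts)
  bad <- which(totals <= 0)
  if (length(bad) > 0L) {
    nm <- colnames(counts)[bad] %||% as.character(bad)
    gp_stop(sprintf("sample(s) with zero total counts: %s",
                    paste(nm, collapse = ", ")),
            "gp_zero_library_error")
  }
  sweep(counts, 2, totals, "/") * 1e6
}
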