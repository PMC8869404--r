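#' qPCR delta-delta-Ct fold changes
#'
#' From a tidy cycle-threshold table, computes per sample and target
#' gene: `dCT = CT_target - CT_housekeeping`, `ddCT = dCT - mean(dCT)`
#' of the reference group, and the fold change `2^-ddCT`. By
#' construction the reference group's mean ddCT is 0 (its fold change
#' at the group mean is exactly 1).
#'
#' @param ct data.frame with columns `sample`, `group`, `gene`, `ct`.
#' @param housekeeping housekeeping gene symbol (e.g. "B2m").
#' @param reference_group reference (control) group label.
#' @return data.frame: `sample`, `group`, `gene`, `dct`,
#'   `rel_expression` (2^-dCT), `ddct`, `fold_change` (2^-ddCT), one
#'   row per sample x target gene.
#' @export
ddct_fold_change <- function(ct, housekeeping, reference_group) {
  gp_assert(is.data.frame(ct) && all(c("sample", "group", "gene", "ct") %in% names(ct)),
            "ct must have columns sample, group, gene, ct")
  gp_assert(reference_group %in% ct$group, "reference_group not present")
  hk <- ct[tolower(ct$gene) == tolower(housekeeping), ]
  gp_assert(nrow(hk) > 0L, sprintf("housekeeping gene '%s' not found", housekeeping))
  targets <- ct[tolower(ct$gene) != tolower(housekeeping), ]
  hk_ct <- setNames(hk$ct, hk$sample)
  no_hk <- setdiff(unique(targets$sample), names(hk_ct))
  if (length(no_hk) > 0L) {
    gp_stop(sprintf("sample(s) missing housekeeping CT: %s",
                    paste(no_hk, collapse = ", ")),
            "gp_missing_housekeeping_error")
  }
  out <- targets
  out$dct <- out$ct - hk_ct[out$sample]
  out$rel_expression <- 2^(-out$dct)
  out$ddct <- NA_real_
  for (g in unique(out$gene)) {
    sel <- out$gene == g
    ref_mean <- mean(out$dct[sel & out$group == reference_group])
    out$ddct[sel] <- out$dct[sel] - ref_mean
  }
  out$fold_change <- 2^(-out$ddct)
  out$ct <- NULL
  rownames(out) <- NULL
  out
}
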