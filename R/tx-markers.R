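#' Marker-panel expression scores and microglial enrichment
#'
#' Scores cell-type marker panels against an RPM matrix: per panel and
#' sample, the mean RPM across the panel's matched genes; the
#' enrichment ratio is the microglia-panel mean divided by the largest
#' other-panel mean (averaged over samples). Gene symbols are matched
#' case-insensitively; unmatched symbols are reported, not silently
#' dropped.
#'
#' @param rpm RPM matrix with gene rownames.
#' @param panels named list of character vectors (one per cell type);
#'   must contain `microglia_panel` (or the panel named by it).
#' @param microglia_panel name of the microglia panel in `panels`.
#' @return list: `panel_means` (panels x samples matrix), `enrichment`
#'   (scalar ratio), `misses` (named list of unmatched symbols).
#' @export
marker_panel_scores <- function(rpm, panels, microglia_panel = "microglia") {
  gp_assert(is.matrix(rpm) && !is.null(rownames(rpm)), "rpm needs gene rownames")
  gp_assert(is.list(panels) && length(panels) >= 1L && !is.null(names(panels)),
            "panels must be a named list")
  gp_assert(microglia_panel %in% names(panels),
            sprintf("no panel named '%s'", microglia_panel))
  key <- tolower(trimws(rownames(rpm)))
  misses <- list()
  panel_means <- matrix(NA_real_, length(panels), ncol(rpm),
                        dimnames = list(names(panels), colnames(rpm)))
  for (pn in names(panels)) {
    want <- trimws(panels[[pn]])
    gp_assert(length(want) > 0L, sprintf("panel '%s' is empty", pn))
    hit <- match(tolower(want), key)
    if (all(is.na(hit))) {
      gp_stop(sprintf("panel '%s' matched no genes in the matrix", pn),
              "gp_empty_panel_error")
    }
    misses[[pn]] <- want[is.na(hit)]
    panel_means[pn, ] <- colMeans(rpm[hit[!is.na(hit)], , drop = FALSE])
  }
  mg <- mean(panel_means[microglia_panel, ])
  others <- setdiff(names(panels), microglia_panel)
  enrichment <- if (length(others) == 0L) NA_real_ else {
    mg / max(rowMeans(panel_means[others, , drop = FALSE]))
  }
  list(panel_means = panel_means, enrichment = enrichment, misses = misses)
}
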