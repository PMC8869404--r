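#' Generate the synthetic study inputs
#'
#' Writes the artifacts the two analysis arms consume: a morphology
#' feature table (default 310 WT + 389 MJD spinal-cord-like cells), a
#' planted-signal count matrix (83 up / 18 down among 20,000 genes, 4
#' vs 4), their truth sidecars, and a run manifest. With
#' `masks = TRUE` a small set of mask images (PNG) is generated as
#' well (slower; off by default).
#'
#' @param out_dir output directory (created; refuses to overwrite
#'   existing files unless `force`).
#' @param config configuration list (see [default_config()]).
#' @param masks also write `n_masks` ramified/activated mask PNGs.
#' @param n_masks number of masks per phenotype when `masks = TRUE`.
#' @param force overwrite existing outputs.
#' @param dry_run write only the manifest describing what would be
#'   generated.
#' @return invisible list of written paths.
#' @export
simulate_study <- function(out_dir, config = default_config(), masks = FALSE,
                           n_masks = 5L, force = FALSE, dry_run = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    features = file.path(out_dir, "features.tsv"),
    feature_truth = file.path(out_dir, "features_truth.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    groups = file.path(out_dir, "groups.tsv"),
    count_truth = file.path(out_dir, "counts_truth.tsv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  if (!force && !dry_run) {
    existing <- unlist(paths[file.exists(unlist(paths))])
    if (length(existing) > 0L) {
      gp_stop(sprintf("output file(s) already exist (use force): %s",
                      paste(existing, collapse = ", ")),
              "gp_path_collision_error")
    }
  }
  if (!dry_run) {
    sim <- simulate_morphology_table(
      n_wt = config$n_wt, n_mjd = config$n_mjd,
      effect_size = config$effect_size, seed = config$seed
    )
    write_feature_table(sim$table, paths$features)
    write_versioned_tsv(sim$truth, paths$feature_truth, "truth")

    cs <- simulate_count_matrix(seed = config$seed)
    write_counts(cs$counts, paths$counts)
    write_group_map(setNames(as.character(cs$groups), colnames(cs$counts)),
                    paths$groups)
    write_versioned_tsv(cs$truth, paths$count_truth, "truth")

    if (masks) {
      mask_dir <- file.path(out_dir, "masks")
      dir.create(mask_dir, showWarnings = FALSE)
      for (i in seq_len(n_masks)) {
        for (ph in c("ramified", "activated")) {
          sm <- simulate_cell_mask(
            phenotype_preset(ph, seed = config$seed + i),
            canvas = 296L, calibration = config$calibration_um_per_px
          )
          write_mask(sm$mask, file.path(mask_dir, sprintf("%s_%03d.png", ph, i)))
        }
      }
      paths$masks <- mask_dir
    }
  }
  write_manifest(paths$manifest, config, paths[names(paths) != "manifest"],
                 stage = "simulate", dry_run = dry_run)
  invisible(paths)
}

#' Morphology arm: masks or feature table to full morphometric report
#'
#' Runs the statistical-learning stage on a feature table (either
#' given directly, read from TSV, or extracted from a directory of
#' mask images): per-feature significance screening, PCA on the
#' selected features, elbow-selected k-means with cluster composition,
#' and nested cross-validated gradient boosted trees with gain
#' importance.
#'
#' @param features a feature table data.frame, a feature-table TSV
#'   path, or a directory of mask images (PNG/TIFF named
#'   `<genotype>_*.png`).
#' @param config configuration list.
#' @param group_column genotype column name.
#' @param run_gbt fit the boosted-tree stage (the slowest step).
#' @return list of class `morphology_report`: `significance`, `pca`,
#'   `elbow`, `composition`, `gbt` (or NULL), `table`.
#' @export
run_morphology_arm <- function(features, config = default_config(),
                               group_column = "genotype", run_gbt = TRUE) {
  table <- if (is.data.frame(features)) {
    features
  } else if (dir.exists(features)) {
    files <- list.files(features, pattern = "\\.(png|tif|tiff)$",
                        full.names = TRUE, ignore.case = TRUE)
    gp_assert(length(files) > 0L,
              sprintf("no mask images found in %s", features))
    masks <- lapply(files, read_mask,
                    calibration = config$calibration_um_per_px)
    meta <- data.frame(
      cell_id = tools::file_path_sans_ext(basename(files)),
      genotype = sub("_.*$", "", basename(files)),
      stringsAsFactors = FALSE
    )
    extract_feature_table(masks, meta)
  } else {
    read_feature_table(features)
  }
  gp_assert(group_column %in% names(table),
            sprintf("missing column '%s' in the feature table", group_column),
            "gp_schema_error")

  sig <- feature_significance(table, group_column, alpha = config$alpha)
  selected <- sig$feature[sig$selected]
  pca_feats <- if (length(selected) >= 3L) selected else
    intersect(morpho_feature_names(), names(table))
  pca <- pca_project(table, features = pca_feats)
  elbow <- elbow_select_k(
    table[, pca_feats, drop = FALSE], k_max = config$k_max,
    rule = config$elbow_rule, n_restarts = config$kmeans_restarts,
    seed = config$seed
  )
  comp <- cluster_composition(
    elbow$fits[[elbow$chosen_k]]$assignments, table[[group_column]]
  )
  gbt <- NULL
  if (run_gbt) {
    gbt <- gbt_nested_cv(
      table, label_column = group_column,
      features = intersect(morpho_feature_names(), names(table)),
      outer = config$cv_outer, inner = config$cv_inner, seed = config$seed
    )
  }
  structure(
    list(significance = sig, selected_features = selected, pca = pca,
         elbow = elbow, composition = comp, gbt = gbt, table = table),
    class = "morphology_report"
  )
}

#' Transcriptomics arm: counts to DEG, overlap and purity reports
#'
#' RPM-normalises a count matrix, calls differential expression with
#' the configured thresholds, and (optionally) computes directional
#' overlap statistics against reference gene sets and marker-panel
#' purity scores.
#'
#' @param counts count matrix (genes x samples) or TSV path.
#' @param groups named group vector (sample -> group), group-map TSV
#'   path, or NULL to take it from `colnames` prefixes.
#' @param config configuration list.
#' @param gene_sets optional named list of direction-annotated
#'   [gene_set()]s to intersect with the DEG list.
#' @param marker_panels optional named list of marker panels for
#'   [marker_panel_scores()].
#' @param case case group label (default second level).
#' @param exclude_samples samples dropped before analysis (explicit
#'   outlier handling).
#' @return list of class `rnaseq_report`: `rpm`, `de`, `degs`,
#'   `overlaps`, `markers`.
#' @export
run_rnaseq_arm <- function(counts, groups = NULL, config = default_config(),
                           gene_sets = NULL, marker_panels = NULL,
                           case = NULL, exclude_samples = character(0)) {
  if (is.character(counts) && length(counts) == 1L) counts <- read_counts(counts)
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    groups <- read_group_map(groups)
  }
  gp_assert(!is.null(groups), "a sample-to-group mapping is required")
  unknown <- setdiff(names(groups), colnames(counts))
  if (length(unknown) > 0L) {
    gp_stop(sprintf("group map contains unknown sample(s): %s",
                    paste(unknown, collapse = ", ")), "gp_schema_error")
  }
  keep <- setdiff(colnames(counts), exclude_samples)
  counts <- counts[, keep, drop = FALSE]
  groups <- groups[keep]
  # levels in order of first appearance: the control group is listed
  # first in the group map; the second level is the case group
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))

  rpm <- rpm_normalize(counts)
  de <- differential_expression(rpm, groups, method = config$de_method,
                                case = case)
  degs <- filter_degs(de, fc_threshold = config$fc_threshold,
                      p_threshold = config$p_threshold,
                      fdr_threshold = config$fdr_threshold)
  deg_set <- gene_set(
    degs$table$gene,
    directions = ifelse(degs$table$fc > 0, "up", "down"),
    name = "DEGs"
  )
  overlaps <- NULL
  if (!is.null(gene_sets)) {
    overlaps <- lapply(gene_sets, function(gs) {
      list(
        fisher = fisher_overlap(deg_set, gs,
                                universe_size = config$universe_size),
        concordance = if (!is.null(gs$directions))
          direction_concordance(deg_set, gs) else NULL
      )
    })
  }
  markers <- if (!is.null(marker_panels))
    marker_panel_scores(rpm, marker_panels) else NULL
  structure(
    list(rpm = rpm, de = de, degs = degs, deg_set = deg_set,
         overlaps = overlaps, markers = markers),
    class = "rnaseq_report"
  )
}

# manifest: config echo + md5 of each artifact
write_manifest <- function(path, config, artifacts, stage, dry_run = FALSE) {
  files <- unlist(artifacts)
  files <- files[!is.na(files) & file.exists(files) & !dir.exists(files)]
  yaml::write_yaml(list(
    stage = stage,
    version = tryCatch(as.character(utils::packageVersion("gliaProfiler")),
                       error = function(e) "dev"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    dry_run = dry_run,
    config = config,
    checksums = as.list(tools::md5sum(files))
  ), path)
  invisible(path)
}
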