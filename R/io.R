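# version tag written as the first comment line of every table format
GP_FORMAT_VERSION <- "gliaProfiler v1"

#' Read and write binary cell masks
#'
#' Masks are stored as 8-bit single-channel PNG or TIFF images with 0
#' background and 255 (or 1.0) foreground. `read_mask()` collapses
#' multi-channel images by taking the first channel.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param mask a [cell_mask()] or binary matrix (for writing).
#' @param calibration micrometres per pixel attached to the mask on
#'   reading.
#' @return `read_mask()`: a [cell_mask()]; `write_mask()`: the path,
#'   invisibly.
#' @export
read_mask <- function(path, calibration = 0.31) {
  gp_assert(file.exists(path), sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    gp_stop(sprintf("unsupported mask format '.%s' (use png/tif/tiff)", ext),
            "gp_format_error")
  )
  if (length(dim(img)) == 3L) img <- img[, , 1]
  cell_mask(img > 0.5, calibration = calibration)
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  m <- as_binary_matrix(mask)
  ext <- tolower(tools::file_ext(path))
  img <- matrix(as.numeric(m), nrow(m), ncol(m))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    gp_stop(sprintf("unsupported mask format '.%s' (use png/tif/tiff)", ext),
            "gp_format_error")
  )
  invisible(path)
}

write_versioned_tsv <- function(df, path, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %s", GP_FORMAT_VERSION, what), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write feature tables
#'
#' Tab-separated tables with a version comment line; columns are the
#' metadata followed by the 25 features of [morpho_feature_names()].
#'
#' @param table feature table data.frame.
#' @param path file path.
#' @param check require all 25 feature columns on read.
#' @return data.frame (read) or the path, invisibly (write).
#' @export
write_feature_table <- function(table, path) {
  write_versioned_tsv(table, path, "feature_table")
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, check = TRUE) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (check) {
    missing <- setdiff(morpho_feature_names(), names(df))
    if (length(missing) > 0L) {
      gp_stop(sprintf("feature table is missing column(s): %s",
                      paste(missing, collapse = ", ")),
              "gp_schema_error")
    }
  }
  df
}

#' Read and write count matrices
#'
#' Genes x samples TSV with a `gene` first column; the sample-to-group
#' mapping travels in a separate two-column TSV (`sample`, `group`).
#'
#' @param counts integer matrix with gene rownames.
#' @param path file path.
#' @return `read_counts()` returns the numeric matrix with rownames.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write_versioned_tsv(df, path, "count_matrix")
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  gp_assert("gene" %in% names(df), "count table needs a 'gene' column",
            "gp_schema_error")
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' @rdname write_counts
#' @param groups named vector or data.frame (`sample`, `group`).
#' @export
write_group_map <- function(groups, path) {
  df <- if (is.data.frame(groups)) groups else
    data.frame(sample = names(groups), group = as.character(groups))
  write_versioned_tsv(df, path, "group_map")
}

#' @rdname write_counts
#' @export
read_group_map <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  gp_assert(all(c("sample", "group") %in% names(df)),
            "group map needs 'sample' and 'group' columns", "gp_schema_error")
  setNames(df$group, df$sample)
}

#' Read gene sets from GMT or two-column CSV
#'
#' `read_gene_set_csv()` reads a `gene,direction` CSV (direction
#' optional) into a single [gene_set()]. `read_gmt()` reads a
#' standard GMT file (set name, description, genes...) into a list of
#' gene sets without directions.
#'
#' @param path file path.
#' @param name set name for the CSV reader (default: file stem).
#' @return a [gene_set()] or a named list of them.
#' @export
read_gene_set_csv <- function(path, name = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  gp_assert("gene" %in% names(df), "gene set CSV needs a 'gene' column",
            "gp_schema_error")
  gp_assert(nrow(df) > 0L, sprintf("gene set file is empty: %s", path),
            "gp_empty_set_error")
  gene_set(df$gene,
           directions = if ("direction" %in% names(df)) df$direction else NULL,
           name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' @rdname read_gene_set_csv
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  gp_assert(length(lines) > 0L, sprintf("gene set file is empty: %s", path),
            "gp_empty_set_error")
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    gp_assert(length(parts) >= 3L, "malformed GMT line (need name, desc, genes)",
              "gp_format_error")
    gene_set(parts[-(1:2)], name = parts[1])
  })
  setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Pipeline configuration
#'
#' YAML-backed configuration holding the seed, calibration, screening
#' alpha, elbow rule, cross-validation settings, DEG thresholds and
#' overlap universe. `default_config()` gives the study defaults;
#' `read_config()`/`write_config()` round-trip losslessly through
#' YAML.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    calibration_um_per_px = 0.31,
    alpha = 0.05,
    elbow_rule = "knee",
    k_max = 12L,
    kmeans_restarts = 10L,
    cv_outer = 5L,
    cv_inner = 5L,
    de_method = "moderated",
    fc_threshold = 1,
    p_threshold = 0.05,
    fdr_threshold = 0.1,
    universe_size = 23930L,
    n_wt = 310L,
    n_mjd = 389L,
    effect_size = 3
  )
}

#' @rdname default_config
#' @param config configuration list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gp_assert(!is.null(cfg$seed), "config must contain an explicit 'seed' field")
  out <- modifyList(default_config(), cfg)
  gp_assert(out$alpha > 0 && out$alpha < 1, "alpha out of range")
  gp_assert(out$fdr_threshold > 0 && out$fdr_threshold <= 1, "fdr_threshold out of range")
  gp_assert(out$p_threshold > 0 && out$p_threshold <= 1, "p_threshold out of range")
  gp_assert(out$calibration_um_per_px > 0, "calibration must be > 0")
  out
}
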