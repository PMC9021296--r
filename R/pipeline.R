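#' Build a pipeline configuration
#'
#' Collects paths, thresholds and seeds for an end-to-end run. When
#' `counts_path` is `NULL` the bulk data are simulated with
#' [simulate_bulk_counts()]; when `cell_dir` is `NULL` the cell table is
#' simulated with [simulate_cell_table()]; when `gmt_path` is `NULL` a
#' gene-set collection with planted category structure is generated from
#' the bulk gene universe.
#'
#' @param out_dir Output directory for all result files.
#' @param counts_path,design_path Optional bulk counts TSV + sample sheet
#'   CSV.
#' @param gmt_path Optional GMT gene-set collection.
#' @param panel Optional character vector of panel genes; defaults to a
#'   deterministic 18-gene subset of the expression matrix.
#' @param cell_dir Optional directory with `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`, `metadata.csv`.
#' @param bulk_alpha DEG threshold for the bulk contrasts.
#' @param marker_alpha Adjusted-p threshold for single-cell markers.
#' @param deges_iterations DEG-elimination rounds during normalization.
#' @param min_umi,max_mito Single-cell QC thresholds.
#' @param seed Integer seed driving every simulated input.
#' @return A `pipeline_config` list, validated.
#' @export
pipeline_config <- function(out_dir,
                            counts_path = NULL, design_path = NULL,
                            gmt_path = NULL, panel = NULL,
                            cell_dir = NULL,
                            bulk_alpha = 0.01, marker_alpha = 0.05,
                            deges_iterations = 3,
                            min_umi = 1000, max_mito = 0.27,
                            seed = 1L) {
  if (bulk_alpha <= 0 || bulk_alpha >= 1) abort("bulk_alpha must be in (0,1)")
  if (marker_alpha <= 0 || marker_alpha >= 1) abort("marker_alpha must be in (0,1)")
  if (deges_iterations < 1) abort("deges_iterations must be >= 1")
  if (min_umi < 0 || max_mito < 0 || max_mito > 1) abort("invalid QC thresholds")
  for (p in c(counts_path, design_path, gmt_path, cell_dir)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("input path not found: %s", p))
  }
  structure(
    list(out_dir = out_dir, counts_path = counts_path,
         design_path = design_path, gmt_path = gmt_path, panel = panel,
         cell_dir = cell_dir, bulk_alpha = bulk_alpha,
         marker_alpha = marker_alpha,
         deges_iterations = as.integer(deges_iterations),
         min_umi = min_umi, max_mito = max_mito, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A validated `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full treatment-rescue pipeline
#'
#' Orchestrates the stages end to end: (simulate or load) bulk counts →
#' DEGES normalization → NB-LRT differential expression for the disease
#' (WT-D vs 3xTg-D) and treated (WT-D vs 3xTg-S) contrasts → rescue
#' classification and restoration magnitude → keyword category curation
#' and category fractions → IEG panel z-scores, down-regulated subset and
#' factorial comparison → (simulate or load) cell table → QC → subcluster
#' composition → activation scores → microglial markers and their rescue
#' classification. Every stage's tables land under `out_dir` and a
#' versioned machine-readable summary is written to
#' `out_dir/summary.json`. Deterministic under the config seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(schema_version = "1.0",
                  package_version = as.character(utils::packageVersion("degrescue")),
                  seed = config$seed,
                  thresholds = list(bulk_alpha = config$bulk_alpha,
                                    marker_alpha = config$marker_alpha,
                                    deges_iterations = config$deges_iterations,
                                    min_umi = config$min_umi,
                                    max_mito = config$max_mito))

  ## ---- bulk counts ----
  if (is.null(config$counts_path)) {
    sim <- simulate_bulk_counts(bulk_sim_spec(seed = config$seed))
    counts <- sim$counts; design <- sim$design
    write_count_matrix(counts, design,
                       file.path(config$out_dir, "counts.tsv"),
                       file.path(config$out_dir, "samples.csv"))
    readr::write_csv(sim$truth, file.path(config$out_dir, "bulk_truth.csv"),
                     progress = FALSE)
  } else {
    loaded <- read_count_matrix(config$counts_path, config$design_path)
    counts <- loaded$counts; design <- loaded$design
  }

  ## ---- normalization + DE, both contrasts ----
  de <- list()
  for (contrast in list(c("WT-D", "3xTg-D"), c("WT-D", "3xTg-S"))) {
    sf <- deges_normalize(counts, design, contrast[1], contrast[2],
                          iterations = config$deges_iterations,
                          alpha = config$bulk_alpha)
    res <- nb_lrt_test(counts, design, contrast[1], contrast[2],
                       size_factors = sf)
    key <- paste(contrast, collapse = "_vs_")
    readr::write_tsv(res, file.path(config$out_dir, paste0("de_", gsub("[^A-Za-z0-9_]", "", key), ".tsv")),
                     progress = FALSE)
    de[[key]] <- list(result = res,
                      degs = call_degs(res, alpha = config$bulk_alpha),
                      size_factors = sf)
  }
  degs_ab <- de[["WT-D_vs_3xTg-D"]]$degs
  degs_as <- de[["WT-D_vs_3xTg-S"]]$degs
  summary$bulk <- list(
    n_genes = nrow(counts),
    degs_disease = nrow(degs_ab),
    degs_disease_up = sum(degs_ab$direction == "up"),
    degs_disease_down = sum(degs_ab$direction == "down"),
    degs_treated = nrow(degs_as))

  ## ---- rescue ----
  rescue <- classify_rescue(degs_ab, degs_as)
  readr::write_csv(as_tibble(rescue), file.path(config$out_dir, "rescue_table.csv"),
                   progress = FALSE)
  counts_rescue <- as.list(table(rescue$label))
  norm <- normalize_counts(counts, de[["WT-D_vs_3xTg-S"]]$size_factors)
  restored <- rescue$gene[rescue$label == "Restored"]
  restoration <- if (length(restored)) {
    rm <- restoration_magnitude(norm, design, restored)
    list(mean_reduction_pct = attr(rm, "mean_reduction_pct"),
         n_excluded = attr(rm, "n_excluded"))
  } else list(mean_reduction_pct = NULL, n_excluded = 0L)
  summary$rescue <- c(counts_rescue,
                      list(restored_fraction = unname(counts_rescue$Restored) /
                             max(1, nrow(degs_ab))),
                      restoration)

  ## ---- categories ----
  if (is.null(config$gmt_path)) {
    gs <- make_gene_sets(counts$gene,
                         plan = tibble(category = c("Lipid", "Immune", "Synapse"),
                                       fragment = c("lipid", "inflammatory", "synaptic"),
                                       prop = c(0.16, 0.26, 0.18)),
                         seed = config$seed)
    sets <- gs$sets
    write_gmt(sets, file.path(config$out_dir, "gene_sets.gmt"))
  } else {
    sets <- read_gmt(config$gmt_path)
  }
  categories <- keyword_curate(sets)
  readr::write_csv(categories, file.path(config$out_dir, "gene_categories.csv"),
                   progress = FALSE)
  if (nrow(degs_as)) {
    fractions <- category_fractions(degs_as, categories)
    summary$categories <- purrr::transpose(
      as.list(fractions[c("category", "n", "percent")]))
  }
  summary$category_rescue <- purrr::transpose(
    as.list(category_rescue_stats(rescue, categories)))

  ## ---- IEG panel ----
  panel <- config$panel
  if (is.null(panel)) panel <- utils::head(sort(counts$gene), 18)
  z <- zscore_matrix(norm, panel)
  readr::write_csv(z, file.path(config$out_dir, "ieg_zscores.csv"), progress = FALSE)
  down <- select_downregulated(de[["WT-D_vs_3xTg-D"]]$result, panel,
                               alpha = config$bulk_alpha)
  summary$ieg <- list(panel_size = length(panel), n_down = length(down))
  if (length(down)) {
    cmp <- panel_group_comparison(norm, design, down)
    summary$ieg$anova <- purrr::transpose(as.list(cmp$anova))
    summary$ieg$dunnett <- purrr::transpose(as.list(cmp$dunnett))
  }

  ## ---- single cell ----
  if (is.null(config$cell_dir)) {
    csim <- simulate_cell_table(cell_sim_spec(seed = config$seed))
    cells <- csim$cells
    write_cell_table(cells, file.path(config$out_dir, "cells"))
  } else {
    cells <- read_cell_table(file.path(config$cell_dir, "matrix.mtx"),
                             file.path(config$cell_dir, "features.tsv"),
                             file.path(config$cell_dir, "barcodes.tsv"),
                             file.path(config$cell_dir, "metadata.csv"))
  }
  cells <- qc_filter_cells(cells, config$min_umi, config$max_mito, quiet = TRUE)
  summary$qc <- attr(cells, "removed")
  props <- subcluster_proportions(cells)
  readr::write_csv(props, file.path(config$out_dir, "subcluster_proportions.csv"),
                   progress = FALSE)
  scores <- activation_score(props)
  jsonlite::write_json(scores, file.path(config$out_dir, "activation_scores.json"),
                       dataframe = "rows", digits = NA)
  summary$activation <- purrr::transpose(as.list(scores))

  markers_ab <- cluster_markers(cells, "WT-D", "3xTg-D", alpha = config$marker_alpha)
  markers_as <- cluster_markers(cells, "WT-D", "3xTg-S", alpha = config$marker_alpha)
  readr::write_tsv(markers_ab, file.path(config$out_dir, "markers_WTD_3xTgD.tsv"),
                   progress = FALSE)
  readr::write_tsv(markers_as, file.path(config$out_dir, "markers_WTD_3xTgS.tsv"),
                   progress = FALSE)
  marker_rescue <- rescue_classify_markers(markers_ab, markers_as,
                                           alpha = config$marker_alpha)
  summary$microglia <- list(
    markers_disease = sum(markers_ab$significant),
    markers_treated = sum(markers_as$significant),
    marker_rescue = as.list(table(marker_rescue$label)))

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
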