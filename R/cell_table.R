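#' Microglial subcluster labels
#'
#' The seven subcluster annotations used throughout the single-cell
#' landscape analysis: two resting/homeostatic states (RH1, RH2), two
#' transitional states and three active states — Active Response (AR),
#' Active Interferon Response (AIR) and Active Synapse-associated Response
#' (ASR).
#'
#' @return Character vector of the seven subcluster labels.
#' @export
microglia_subclusters <- function() {
  c("RH1", "RH2", "T(AR/AIR)", "T(ASR)", "AR", "AIR", "ASR")
}

#' Default lineage map for activation scoring
#'
#' Resting cells are RH1 + RH2; the AR/AIR lineage is its transitional
#' state plus AR and AIR; the ASR lineage is its transitional state plus
#' ASR.
#'
#' @return List with `resting` (character vector) and `lineages` (named
#'   list of character vectors).
#' @export
lineage_default_map <- function() {
  list(resting = c("RH1", "RH2"),
       lineages = list(
         `AR/AIR` = c("T(AR/AIR)", "AR", "AIR"),
         ASR = c("T(ASR)", "ASR")))
}

#' Construct a sparse cell table
#'
#' Bundles a sparse gene-by-cell count matrix with per-cell metadata. The
#' metadata must carry one row per cell (keyed by `barcode`) with the
#' experimental group, cluster and subcluster labels, the UMI count and
#' the mitochondrial fraction.
#'
#' @param counts A gene x cell `dgCMatrix` (or coercible sparse matrix)
#'   with row and column names.
#' @param meta Tibble with columns `barcode`, `group`, `cluster`,
#'   `subcluster`, `umi_count`, `mito_fraction`, one row per column of
#'   `counts`.
#' @return A `cell_table` list with elements `counts` and `meta` (meta
#'   ordered to match the matrix columns).
#' @export
cell_table <- function(counts, meta) {
  counts <- if (is.matrix(counts)) {
    Matrix::Matrix(counts, sparse = TRUE)
  } else {
    methods::as(counts, "CsparseMatrix")
  }
  need <- c("barcode", "group", "cluster", "subcluster", "umi_count", "mito_fraction")
  if (!all(need %in% names(meta))) {
    abort(sprintf("meta must have columns: %s", paste(need, collapse = ", ")))
  }
  if (is.null(rownames(counts)) || (is.null(colnames(counts)) && ncol(counts) > 0)) {
    abort("counts must have gene rownames and cell colnames")
  }
  if (!setequal(colnames(counts), meta$barcode) ||
      ncol(counts) != nrow(meta)) {
    abort("meta barcodes must match count matrix columns exactly")
  }
  if (any(meta$mito_fraction < 0 | meta$mito_fraction > 1)) {
    abort("mito_fraction must lie in [0, 1]")
  }
  meta <- as_tibble(meta)[match(colnames(counts), meta$barcode), ]
  structure(list(counts = counts, meta = meta), class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat("cell_table: ", nrow(x$counts), " genes x ", ncol(x$counts), " cells\n",
      sep = "")
  print(dplyr::count(x$meta, .data$group, .data$cluster))
  invisible(x)
}

#' @export
dim.cell_table <- function(x) dim(x$counts)

#' Specify a synthetic labelled single-cell experiment
#'
#' Describes a multiplexed hippocampal single-cell dataset dominated by a
#' microglia cluster split into the seven subclusters of
#' [microglia_subclusters()]. Per group, subcluster identity is drawn
#' multinomially; each cell's UMI total is log-normal; its gene counts are
#' a multinomial over a fixed background expression profile, with each
#' subcluster's marker genes elevated by a fold factor; its mitochondrial
#' fraction is Beta-distributed with a subcluster-specific mean.
#'
#' Default subcluster proportions for the WT-D group follow the reported
#' composition of a healthy control hippocampus (43% resting split 28/15,
#' 27/2/2% along the AR/AIR lineage, 19/7% along the ASR lineage); the
#' other groups default to plausible disease/treatment shifts toward the
#' active states.
#'
#' @param n_cells_per_group Named integer vector of cells per group.
#' @param subcluster_proportions Matrix (group x subcluster) of
#'   probabilities; rows must sum to 1.
#' @param n_genes Number of background genes (markers included).
#' @param markers_per_subcluster Number of marker genes elevated per
#'   subcluster.
#' @param marker_fold Fold elevation of marker genes in their subcluster.
#' @param umi_meanlog,umi_sdlog Log-normal parameters of per-cell UMI
#'   totals.
#' @param mito_mean Named numeric: mean mitochondrial fraction per
#'   subcluster (recycled if length 1).
#' @param mito_conc Beta concentration (a + b) for the mito fraction.
#' @param seed Integer seed.
#' @return A `cell_sim_spec` list, validated.
#' @export
cell_sim_spec <- function(n_cells_per_group = c("WT-D" = 800, "3xTg-D" = 800,
                                                "WT-S" = 800, "3xTg-S" = 800),
                          subcluster_proportions = default_subcluster_proportions(),
                          n_genes = 120,
                          markers_per_subcluster = 3,
                          marker_fold = 8,
                          umi_meanlog = log(4000),
                          umi_sdlog = 0.45,
                          mito_mean = 0.08,
                          mito_conc = 30,
                          seed = 1L) {
  if (any(n_cells_per_group < 1)) abort("n_cells_per_group must be positive")
  if (is.null(names(n_cells_per_group))) abort("n_cells_per_group must be named by group")
  subcluster_proportions <- as.matrix(subcluster_proportions)
  if (!setequal(colnames(subcluster_proportions), microglia_subclusters())) {
    abort("subcluster_proportions columns must be the seven subclusters")
  }
  if (!all(names(n_cells_per_group) %in% rownames(subcluster_proportions))) {
    abort("every group needs a row in subcluster_proportions")
  }
  if (any(abs(rowSums(subcluster_proportions) - 1) > 1e-8)) {
    abort("each group's subcluster proportions must sum to 1")
  }
  if (any(subcluster_proportions < 0)) abort("proportions must be non-negative")
  mito_mean <- rep_len(mito_mean, 7)
  names(mito_mean) <- microglia_subclusters()
  structure(
    list(n_cells_per_group = n_cells_per_group,
         subcluster_proportions = subcluster_proportions[, microglia_subclusters(), drop = FALSE],
         n_genes = as.integer(n_genes),
         markers_per_subcluster = as.integer(markers_per_subcluster),
         marker_fold = marker_fold,
         umi_meanlog = umi_meanlog, umi_sdlog = umi_sdlog,
         mito_mean = mito_mean, mito_conc = mito_conc,
         seed = as.integer(seed)),
    class = "cell_sim_spec")
}

#' Default per-group microglial subcluster proportions
#'
#' @return Group x subcluster probability matrix (rows sum to 1).
#' @export
default_subcluster_proportions <- function() {
  m <- rbind(
    "WT-D"   = c(28, 15, 27, 19,  2,  2,  7),
    "3xTg-D" = c(15,  8, 30, 20, 10,  7, 10),
    "WT-S"   = c(27, 16, 26, 19,  3,  2,  7),
    "3xTg-S" = c(22, 12, 28, 20,  6,  4,  8)) / 100
  colnames(m) <- microglia_subclusters()
  m
}

#' Simulate a labelled cell table with ground truth
#'
#' Draws cells group by group under a [cell_sim_spec()]. Every cell's UMI
#' count equals its column sum by construction (counts are multinomial
#' given the UMI total). Marker genes are named `Mk_<subcluster>_<i>`;
#' background genes `bg0001` onward.
#'
#' @param spec A [cell_sim_spec()].
#' @return A list of class `cell_sim` with `cells` (a [cell_table()]),
#'   `truth` (tibble: `barcode`, `group`, `subcluster`) and
#'   `marker_genes` (tibble: `gene`, `subcluster`, `fold`).
#' @export
simulate_cell_table <- function(spec) {
  stopifnot(inherits(spec, "cell_sim_spec"))
  subs <- microglia_subclusters()
  withr::with_seed(spec$seed, {
    n_marker <- spec$markers_per_subcluster * length(subs)
    if (spec$n_genes <= n_marker) abort("n_genes must exceed the marker count")
    marker_tbl <- tibble(
      gene = unlist(lapply(subs, function(s)
        sprintf("Mk_%s_%d", gsub("[^A-Za-z0-9]", "", s), seq_len(spec$markers_per_subcluster)))),
      subcluster = rep(subs, each = spec$markers_per_subcluster),
      fold = spec$marker_fold)
    genes <- c(marker_tbl$gene, sprintf("bg%04d", seq_len(spec$n_genes - n_marker)))

    # fixed background expression profile, heavier tail like real libraries
    base_w <- stats::rgamma(length(genes), shape = 0.6, rate = 1) + 0.05

    groups <- names(spec$n_cells_per_group)
    blocks <- list(); metas <- list(); cell_id <- 0L
    for (g in groups) {
      n <- spec$n_cells_per_group[[g]]
      p <- spec$subcluster_proportions[g, ]
      sub <- sample(subs, n, replace = TRUE, prob = p)
      umi <- pmax(round(stats::rlnorm(n, spec$umi_meanlog, spec$umi_sdlog)), 50)
      mm <- spec$mito_mean[sub]
      mito <- stats::rbeta(n, mm * spec$mito_conc, (1 - mm) * spec$mito_conc)
      cnt <- matrix(0L, length(genes), n)
      for (s in subs) {
        idx <- which(sub == s)
        if (!length(idx)) next
        w <- base_w
        mk <- marker_tbl$gene[marker_tbl$subcluster == s]
        w[match(mk, genes)] <- w[match(mk, genes)] * spec$marker_fold
        for (i in idx) cnt[, i] <- stats::rmultinom(1, umi[i], w)
      }
      barcodes <- sprintf("cell%06d", cell_id + seq_len(n))
      cell_id <- cell_id + n
      dimnames(cnt) <- list(genes, barcodes)
      blocks[[g]] <- Matrix::Matrix(cnt, sparse = TRUE)
      metas[[g]] <- tibble(barcode = barcodes, group = g,
                           cluster = "microglia", subcluster = sub,
                           umi_count = colSums(cnt), mito_fraction = mito)
    }
    counts <- do.call(cbind, blocks)
    meta <- dplyr::bind_rows(metas)
    cells <- cell_table(counts, meta)
    list(cells = cells,
         truth = meta[, c("barcode", "group", "subcluster")],
         marker_genes = marker_tbl) |>
      structure(class = "cell_sim")
  })
}
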