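#' Quality-control filter on cells
#'
#' Retains cells with `umi_count >= min_umi` and `mito_fraction <=
#' max_mito` (both thresholds inclusive on the keep side). The numbers of
#' cells removed by each criterion are recorded in the `removed` attribute
#' and reported via a message.
#'
#' @param cells A [cell_table()].
#' @param min_umi Minimum UMI count to keep a cell.
#' @param max_mito Maximum mitochondrial fraction to keep a cell.
#' @param quiet Suppress the removal message.
#' @return The filtered `cell_table`; attribute `removed` is a named list
#'   with counts `low_umi`, `high_mito`, `total_removed`.
#' @export
qc_filter_cells <- function(cells, min_umi = 1000, max_mito = 0.27,
                            quiet = FALSE) {
  stopifnot(inherits(cells, "cell_table"))
  keep_umi <- cells$meta$umi_count >= min_umi
  keep_mito <- cells$meta$mito_fraction <= max_mito
  keep <- keep_umi & keep_mito
  removed <- list(low_umi = sum(!keep_umi), high_mito = sum(!keep_mito),
                  total_removed = sum(!keep))
  out <- structure(list(counts = cells$counts[, keep, drop = FALSE],
                        meta = cells$meta[keep, , drop = FALSE]),
                   class = "cell_table")
  if (!quiet) {
    message(sprintf("QC: removed %d cells (%d below %d UMIs, %d above %.0f%% mito); %d kept",
                    removed$total_removed, removed$low_umi, min_umi,
                    removed$high_mito, 100 * max_mito, sum(keep)))
  }
  attr(out, "removed") <- removed
  out
}

#' Subcluster composition per group
#'
#' Tabulates, within one cluster (microglia by default), the percentage of
#' each group's cells falling in each of the seven subclusters. Rows for a
#' group sum to 100.
#'
#' @param cells A [cell_table()].
#' @param cluster Cluster label to restrict to.
#' @param subclusters Subcluster levels to tabulate over (zero counts are
#'   reported, extra labels in the data error).
#' @return Tibble: `group`, `subcluster`, `n`, `percent`.
#' @export
subcluster_proportions <- function(cells, cluster = "microglia",
                                   subclusters = microglia_subclusters()) {
  stopifnot(inherits(cells, "cell_table"))
  meta <- cells$meta[cells$meta$cluster == cluster, ]
  if (nrow(meta) == 0) abort(sprintf("no cells in cluster '%s'", cluster))
  groups <- unique(cells$meta$group)
  empty <- setdiff(groups, unique(meta$group))
  if (length(empty)) {
    abort(sprintf("group(s) with zero '%s' cells: %s", cluster,
                  paste(empty, collapse = ", ")))
  }
  extra <- setdiff(unique(meta$subcluster), subclusters)
  if (length(extra)) {
    abort(sprintf("unknown subcluster label(s): %s", paste(extra, collapse = ", ")))
  }
  meta |>
    dplyr::count(.data$group, subcluster = factor(.data$subcluster, levels = subclusters),
                 .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(subcluster = as.character(.data$subcluster))
}

#' Lineage activation scores
#'
#' For each group and lineage, the lineage-positive cells (transitional +
#' active states) expressed as a percentage of the resting cells
#' (RH1 + RH2): a score of 100 means parity between lineage-positive and
#' resting cells. Identical whether computed from raw cell counts or from
#' a percentage table (the resting denominator cancels the scale).
#'
#' @param x Either a [cell_table()] or a proportions tibble from
#'   [subcluster_proportions()] (any column named `n` or `percent` is
#'   used, in that order).
#' @param lineage_map A [lineage_default_map()]-shaped list.
#' @param cluster Cluster restriction when `x` is a `cell_table`.
#' @return Tibble: `group`, `lineage`, `score`.
#' @export
activation_score <- function(x, lineage_map = lineage_default_map(),
                             cluster = "microglia") {
  if (inherits(x, "cell_table")) {
    x <- subcluster_proportions(x, cluster = cluster,
                                subclusters = unique(c(microglia_subclusters(),
                                                       unlist(lineage_map))))
  }
  stopifnot(all(c("group", "subcluster") %in% names(x)))
  val_col <- if ("n" %in% names(x)) "n" else if ("percent" %in% names(x)) "percent"
  else abort("x must have an 'n' or 'percent' column")
  if (length(intersect(lineage_map$resting, unlist(lineage_map$lineages)))) {
    abort("resting and lineage subcluster sets must be disjoint")
  }
  per_group <- split(x, x$group)
  rows <- purrr::imap(per_group, function(df, g) {
    val <- stats::setNames(df[[val_col]], df$subcluster)
    resting <- sum(val[lineage_map$resting], na.rm = TRUE)
    if (resting <= 0) abort(sprintf("group '%s' has zero resting cells", g))
    tibble(group = g,
           lineage = names(lineage_map$lineages),
           score = unname(purrr::map_dbl(lineage_map$lineages,
                                         ~ 100 * sum(val[.x], na.rm = TRUE) / resting)))
  })
  dplyr::bind_rows(rows)
}

# --- rank-sum machinery -----------------------------------------------------

# Two-sided Wilcoxon rank-sum p-value with mid-ranks.
# Exact enumeration of all C(n1+n2, n1) assignments when the smaller group
# has <= exact_limit members; otherwise normal approximation with tie
# correction and continuity correction. `comb` may carry a precomputed
# combn(n1 + n2, n1) matrix to share across genes.
rank_sum_p <- function(a, b, exact_limit = 8, comb = NULL) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  e <- n1 * (n + 1) / 2
  if (min(n1, n2) <= exact_limit) {
    if (is.null(comb)) comb <- utils::combn(n, n1)
    ws <- colSums(matrix(r[comb], nrow = n1))
    return(mean(abs(ws - e) >= abs(w - e) - 1e-9))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(w - e) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-z))
}

#' Per-cluster marker genes between two groups
#'
#' Within one cluster, tests every gene between two groups with a
#' two-sided Wilcoxon rank-sum test on normalized expression (per-cell
#' counts scaled to a common total, then natural-log(1 + x)). P-values are
#' Bonferroni-adjusted across tested genes by default. The fold change is
#' the natural log of the ratio of group mean normalized expression
#' (B over A).
#'
#' For groups of at most 8 cells the rank-sum p-value is computed by
#' exhaustive enumeration of group assignments (exact under ties); larger
#' groups use the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param cells A [cell_table()].
#' @param group_a,group_b Group labels to contrast (fold change is B over
#'   A).
#' @param cluster Cluster restriction.
#' @param scale_total Common per-cell total for normalization.
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @param alpha Adjusted-p significance threshold recorded in the
#'   `significant` column.
#' @return A `marker_result` tibble: `gene`, `mean_a`, `mean_b`,
#'   `log_fc`, `p`, `p_adj`, `significant`, ordered by ascending `p` then
#'   gene.
#' @export
cluster_markers <- function(cells, group_a, group_b, cluster = "microglia",
                            scale_total = 1e4,
                            adjust = c("bonferroni", "BH"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(cells, "cell_table"))
  in_cluster <- cells$meta$cluster == cluster
  if (!any(in_cluster)) abort(sprintf("cluster '%s' not present", cluster))
  idxA <- which(in_cluster & cells$meta$group == group_a)
  idxB <- which(in_cluster & cells$meta$group == group_b)
  if (length(idxA) < 3 || length(idxB) < 3) {
    abort("need at least 3 cells per group within the cluster")
  }
  m <- cells$counts[, c(idxA, idxB), drop = FALSE]
  totals <- Matrix::colSums(m)
  totals[totals == 0] <- 1
  norm <- m %*% Matrix::Diagonal(x = scale_total / totals)
  lognorm <- as.matrix(norm)
  isA <- seq_along(c(idxA, idxB)) <= length(idxA)
  logn <- log1p(lognorm)

  n1 <- sum(isA); n2 <- sum(!isA)
  comb <- if (min(n1, n2) <= 8) utils::combn(n1 + n2, n1) else NULL
  p <- vapply(seq_len(nrow(logn)), function(i)
    rank_sum_p(logn[i, isA], logn[i, !isA], comb = comb), numeric(1))

  mean_a <- rowMeans(lognorm[, isA, drop = FALSE])
  mean_b <- rowMeans(lognorm[, !isA, drop = FALSE])
  eps <- 1e-9
  out <- tibble(
    gene = rownames(m),
    mean_a = mean_a, mean_b = mean_b,
    log_fc = log((mean_b + eps) / (mean_a + eps)),
    p = p,
    p_adj = stats::p.adjust(p, method = ifelse(adjust == "BH", "BH", "bonferroni")))
  out$significant <- out$p_adj <= alpha
  out <- out[order(out$p, out$gene), , drop = FALSE]
  class(out) <- c("marker_result", class(out))
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  attr(out, "cluster") <- cluster
  out
}

#' Rescue classification of cluster marker lists
#'
#' Applies [classify_rescue()] to two [cluster_markers()] results,
#' thresholded at adjusted p <= `alpha`.
#'
#' @param markers_ab Marker result for the disease contrast.
#' @param markers_as Marker result for the treated contrast.
#' @param alpha Adjusted-p threshold defining each DEG list.
#' @return A `rescue_table` (see [classify_rescue()]).
#' @export
rescue_classify_markers <- function(markers_ab, markers_as, alpha = 0.05) {
  classify_rescue(markers_ab$gene[markers_ab$p_adj <= alpha],
                  markers_as$gene[markers_as$p_adj <= alpha])
}
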