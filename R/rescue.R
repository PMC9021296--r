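#' Classify DEGs into Restored / Maintained / New rescue classes
#'
#' Given the disease-contrast DEG list A (control vs disease, vehicle) and
#' the treated-contrast DEG list B (control vs disease, treated), labels
#' every gene in their union:
#'
#' * **Restored** (A \ B): significant in disease, no longer after treatment;
#' * **Maintained** (A intersect B): significant in both;
#' * **New** (B \ A): newly significant after treatment.
#'
#' Direction is ignored by default (the Venn operates on lists); with
#' `signed = TRUE` a gene whose DE direction flips between contrasts is not
#' Maintained but counted as Restored-and-New, matching a strict signed
#' reading. Signed mode requires data-frame inputs with a `direction`
#' column.
#'
#' @param degs_ab DEG list for the disease contrast (character vector or
#'   [call_degs()] tibble).
#' @param degs_as DEG list for the treated contrast.
#' @param signed Require the same direction for a Maintained call.
#' @return A `rescue_table` tibble: `gene`, `label` (factor
#'   Restored/Maintained/New), `in_a`, `in_b`.
#' @export
#' @examples
#' classify_rescue(c("g1", "g2", "g3"), c("g2", "g4"))
classify_rescue <- function(degs_ab, degs_as, signed = FALSE) {
  a <- as_gene_vector(degs_ab, "degs_ab")
  b <- as_gene_vector(degs_as, "degs_as")
  if (anyDuplicated(a)) abort("duplicate gene IDs in degs_ab")
  if (anyDuplicated(b)) abort("duplicate gene IDs in degs_as")
  maintained <- intersect(a, b)
  if (signed && length(maintained)) {
    if (!is.data.frame(degs_ab) || !is.data.frame(degs_as) ||
        !"direction" %in% names(degs_ab) || !"direction" %in% names(degs_as)) {
      abort("signed = TRUE needs data-frame inputs with a 'direction' column")
    }
    dir_a <- degs_ab$direction[match(maintained, a)]
    dir_b <- degs_as$direction[match(maintained, b)]
    flipped <- maintained[dir_a != dir_b]
    maintained <- setdiff(maintained, flipped)
  } else {
    flipped <- character()
  }
  restored <- c(setdiff(a, b), flipped)
  new <- c(setdiff(b, a), flipped)
  out <- tibble(
    gene = c(restored, maintained, new),
    label = factor(c(rep("Restored", length(restored)),
                     rep("Maintained", length(maintained)),
                     rep("New", length(new))),
                   levels = c("Restored", "Maintained", "New")))
  out$in_a <- out$gene %in% a
  out$in_b <- out$gene %in% b
  out <- out[order(out$label, out$gene), , drop = FALSE]
  class(out) <- c("rescue_table", class(out))
  attr(out, "n_a") <- length(a)
  attr(out, "n_b") <- length(b)
  out
}

#' Restoration magnitude of rescued genes
#'
#' For each restored gene, how far treatment moved the disease expression
#' back toward control, as a percentage of the original disease–control
#' gap measured on `log2(normalized mean + 1)`:
#' `100 * (1 - |m_treated - m_control| / |m_disease - m_control|)`.
#' 100 means full return to the control mean, 0 means no movement, negative
#' values mean overshoot beyond the original gap. Genes whose
#' disease–control gap is below `tol` on the log scale are excluded from
#' the mean and counted.
#'
#' @param norm_expr Normalized expression tibble (`gene` + sample columns),
#'   e.g. from [normalize_counts()].
#' @param design Sample sheet tibble.
#' @param restored_genes Character vector (or data frame) of genes to score.
#' @param groups Named character vector with entries `control`, `disease`,
#'   `treated` giving the three group labels.
#' @param tol Minimum |disease - control| log-gap for a gene to be scored.
#' @return A `restoration_summary` tibble (`gene`, `reduction_pct`,
#'   `excluded`); attributes `mean_reduction_pct` and `n_excluded`.
#' @export
restoration_magnitude <- function(norm_expr, design, restored_genes,
                                  groups = c(control = "WT-D",
                                             disease = "3xTg-D",
                                             treated = "3xTg-S"),
                                  tol = 1e-6) {
  genes <- as_gene_vector(restored_genes, "restored_genes")
  if (length(genes) == 0) abort("restored_genes is empty")
  stopifnot(all(c("control", "disease", "treated") %in% names(groups)))
  design <- check_design(norm_expr, design)
  grp <- design_group(design)
  if (!all(groups %in% grp)) abort("all three groups must be present in design")
  y <- counts_to_matrix(norm_expr)
  missing <- setdiff(genes, rownames(y))
  if (length(missing)) {
    abort(sprintf("genes absent from norm_expr: %s", paste(missing, collapse = ", ")))
  }
  y <- y[genes, , drop = FALSE]
  gm <- function(g) log2(rowMeans(y[, grp == groups[[g]], drop = FALSE]) + 1)
  mc <- gm("control"); md <- gm("disease"); mt <- gm("treated")
  gap <- abs(md - mc)
  excluded <- gap < tol
  reduction <- ifelse(excluded, NA_real_, 100 * (1 - abs(mt - mc) / gap))
  out <- tibble(gene = genes, reduction_pct = unname(reduction),
                excluded = unname(excluded))
  class(out) <- c("restoration_summary", class(out))
  attr(out, "mean_reduction_pct") <- mean(reduction[!excluded])
  attr(out, "n_excluded") <- sum(excluded)
  out
}

#' Rescue statistics by functional category
#'
#' Crosses a rescue table with a gene-to-category map and reports, per
#' category, the Restored/Maintained/New counts among that category's genes
#' and the restored percentage of the category's disease-contrast DEGs
#' (Restored + Maintained), rounded half away from zero. Categories with no
#' disease-contrast DEGs get `NA`.
#'
#' @param rescue A [classify_rescue()] table.
#' @param categories Tibble with columns `gene` and `category` (a gene may
#'   appear under several categories).
#' @return Tibble: `category`, `restored`, `maintained`, `new`, `a_degs`,
#'   `restored_pct`.
#' @export
category_rescue_stats <- function(rescue, categories) {
  stopifnot(all(c("gene", "category") %in% names(categories)))
  joined <- dplyr::inner_join(as_tibble(rescue), dplyr::distinct(categories),
                              by = "gene", relationship = "many-to-many")
  out <- joined |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      restored = sum(.data$label == "Restored"),
      maintained = sum(.data$label == "Maintained"),
      new = sum(.data$label == "New"),
      .groups = "drop") |>
    dplyr::mutate(
      a_degs = .data$restored + .data$maintained,
      restored_pct = ifelse(.data$a_degs > 0,
                            round_half_up(100 * .data$restored / .data$a_degs),
                            NA_real_))
  out
}

#' Overlap of multiple DEG lists
#'
#' Builds the per-gene membership matrix across two or more named DEG lists
#' (e.g. disease models), the consensus set present in every list, and all
#' pairwise intersection sizes.
#'
#' @param lists Named list of two or more non-empty DEG lists (character
#'   vectors or data frames with a `gene` column).
#' @return A list with `membership` (tibble: `gene`, one logical column per
#'   list, `n_lists`), `consensus` (character vector, sorted), and
#'   `pairwise` (named numeric matrix of intersection sizes).
#' @export
multi_list_overlap <- function(lists) {
  if (!is.list(lists) || length(lists) < 2) abort("need at least 2 DEG lists")
  if (is.null(names(lists)) || any(names(lists) == "")) abort("lists must be named")
  vecs <- purrr::map(lists, as_gene_vector)
  if (any(lengths(vecs) == 0)) abort("all lists must be non-empty")
  universe <- sort(unique(unlist(vecs)))
  membership <- tibble(gene = universe)
  for (nm in names(vecs)) membership[[nm]] <- universe %in% vecs[[nm]]
  membership$n_lists <- rowSums(as.matrix(membership[names(vecs)]))
  consensus <- membership$gene[membership$n_lists == length(vecs)]
  pairwise <- outer(names(vecs), names(vecs),
                    Vectorize(function(i, j) length(intersect(vecs[[i]], vecs[[j]]))))
  dimnames(pairwise) <- list(names(vecs), names(vecs))
  list(membership = membership, consensus = consensus, pairwise = pairwise)
}
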