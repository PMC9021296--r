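#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed as the median of each sample's
#' ratios to the per-gene geometric-mean reference, over genes with no zero
#' count, then rescaled so the factors have geometric mean 1.
#'
#' @param counts Tibble with a `gene` column plus one integer column per
#'   sample.
#' @param zero_policy What to do when no gene is zero-free: `"strict"`
#'   (default) errors with instructions, `"pseudo"` adds a 0.5 pseudocount
#'   to every cell when forming the reference so all genes contribute.
#' @return Tibble with `sample_id` and `size_factor` (geometric mean 1).
#' @export
#' @examples
#' counts <- tibble::tibble(gene = c("g1", "g2", "g3"),
#'                          s1 = c(2L, 4L, 8L), s2 = c(4L, 8L, 16L))
#' size_factors(counts)
size_factors <- function(counts, zero_policy = c("strict", "pseudo")) {
  zero_policy <- match.arg(zero_policy)
  y <- counts_to_matrix(counts)
  if (any(y < 0) || any(y != floor(y))) abort("counts must be non-negative integers")
  zero_free <- rowSums(y == 0) == 0
  if (!any(zero_free)) {
    if (zero_policy == "strict") {
      abort(paste("no gene has all-positive counts; rerun with",
                  "zero_policy = \"pseudo\" to use a pseudo-reference"))
    }
    y <- y + 0.5
    zero_free <- rep(TRUE, nrow(y))
  }
  yy <- y[zero_free, , drop = FALSE]
  ref <- exp(rowMeans(log(yy)))
  sf <- apply(yy / ref, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  tibble(sample_id = colnames(y), size_factor = unname(sf))
}

#' DEGES iterative normalization
#'
#' Iteratively removes putative differentially expressed genes before
#' recomputing median-of-ratios size factors, so highly asymmetric DE does
#' not bias the scaling. Each iteration (default 3) tests all genes between
#' the two groups with the package's NB likelihood-ratio test at `alpha`,
#' then recomputes factors on the genes not called DE.
#'
#' @inheritParams size_factors
#' @param design Sample sheet tibble (`sample_id`, `genotype`, `treatment`).
#' @param group_a,group_b Group labels, e.g. `"WT-D"` and `"3xTg-D"`.
#' @param iterations Number of elimination rounds (>= 1).
#' @param alpha Putative-DEG threshold used for elimination (p <= alpha);
#'   `alpha = 0` disables elimination, reducing to [size_factors()].
#' @return Tibble with `sample_id`, `size_factor`; attribute
#'   `genes_retained` holds the gene IDs used in the final round.
#' @export
deges_normalize <- function(counts, design, group_a, group_b,
                            iterations = 3, alpha = 0.01,
                            zero_policy = "strict") {
  if (iterations < 1) abort("iterations must be >= 1")
  sf <- size_factors(counts, zero_policy = zero_policy)
  keep <- counts$gene
  for (i in seq_len(iterations)) {
    de <- nb_lrt_test(counts, design, group_a, group_b, size_factors = sf)
    deg <- de$gene[de$p <= alpha]
    keep <- setdiff(counts$gene, deg)
    if (length(keep) == 0) {
      abort("every gene was flagged as differentially expressed; cannot normalize")
    }
    sf <- size_factors(counts[counts$gene %in% keep, , drop = FALSE],
                       zero_policy = zero_policy)
  }
  attr(sf, "genes_retained") <- keep
  sf
}
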