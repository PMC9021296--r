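#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import methods
NULL

#' Round half away from zero
#'
#' Integer rounding used for every reported percentage: halves round away
#' from zero (so 39.5 -> 40, -0.5 -> -1), unlike [base::round()]'s
#' round-half-even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length, rounded to integers.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5, 24.59, 15.89))
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' The four experimental groups
#'
#' Group labels follow `<genotype>-<treatment>`: genotype WT or 3xTg,
#' treatment D (vehicle) or S (SCD-inhibitor).
#'
#' @return Character vector of the four group labels.
#' @export
study_groups <- function() {
  c("WT-D", "3xTg-D", "WT-S", "3xTg-S")
}

# group label from a design tibble (genotype, treatment)
design_group <- function(design) {
  paste(design$genotype, design$treatment, sep = "-")
}

# counts tibble (gene + sample columns) -> integer matrix with rownames
counts_to_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "gene" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "gene")])
  storage.mode(m) <- "double"
  rownames(m) <- counts$gene
  m
}

matrix_to_counts <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene = rownames(m)), out)
}

# resolve a DEG list given as character vector or data frame with a gene column
as_gene_vector <- function(x, arg = "gene list") {
  if (is.character(x)) return(x)
  if (is.data.frame(x) && "gene" %in% names(x)) return(as.character(x$gene))
  abort(sprintf("%s must be a character vector or a data frame with a 'gene' column", arg))
}

check_design <- function(counts, design) {
  samples <- setdiff(names(counts), "gene")
  if (!all(c("sample_id", "genotype", "treatment") %in% names(design))) {
    abort("design must have columns sample_id, genotype, treatment")
  }
  missing <- setdiff(samples, design$sample_id)
  if (length(missing)) {
    abort(sprintf("samples absent from design: %s", paste(missing, collapse = ", ")))
  }
  design[match(samples, design$sample_id), , drop = FALSE]
}
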