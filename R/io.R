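# Interchange formats: counts TSV + sample-sheet CSV, GMT gene sets,
# Matrix Market cell tables, one-gene-per-line DEG lists.

#' Read a bulk count matrix and its sample sheet
#'
#' The counts TSV has genes as rows (first column `gene`) and one integer
#' column per sample; the sample sheet CSV has columns `sample_id`,
#' `genotype`, `treatment`. Non-integer cells, duplicate gene IDs and
#' samples missing from the sheet are rejected with informative errors.
#'
#' @param counts_path Path to the counts TSV.
#' @param design_path Path to the sample-sheet CSV.
#' @return List with `counts` (tibble) and `design` (tibble).
#' @export
read_count_matrix <- function(counts_path, design_path) {
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE, progress = FALSE)
  if (names(counts)[1] != "gene") abort("first column of counts TSV must be 'gene'")
  dup <- counts$gene[duplicated(counts$gene)]
  if (length(dup)) {
    abort(sprintf("duplicate gene ID(s): %s", paste(unique(dup), collapse = ", ")))
  }
  vals <- counts[-1]
  bad <- which(!purrr::map_lgl(vals, ~ is.numeric(.x) && all(.x == floor(.x) & .x >= 0)))
  if (length(bad)) {
    abort(sprintf("non-integer or negative counts in column(s): %s",
                  paste(names(vals)[bad], collapse = ", ")))
  }
  design <- readr::read_csv(design_path, show_col_types = FALSE, progress = FALSE)
  design <- check_design(counts, design)
  list(counts = counts, design = as_tibble(design))
}

#' Write a bulk count matrix and its sample sheet
#'
#' @param counts Counts tibble (`gene` + sample columns).
#' @param design Sample-sheet tibble.
#' @inheritParams read_count_matrix
#' @return Invisibly, the two paths.
#' @export
write_count_matrix <- function(counts, design, counts_path, design_path) {
  readr::write_tsv(counts, counts_path, progress = FALSE)
  readr::write_csv(design, design_path, progress = FALSE)
  invisible(c(counts_path, design_path))
}

#' Read / write GMT gene-set collections
#'
#' GMT: one set per line — name, description, then member genes, all
#' tab-separated.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort("malformed GMT line (need name, description, >=1 gene)")
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (anyDuplicated(names(out))) abort("duplicate set names in GMT")
  out
}

#' @param sets Named list of gene sets.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a sparse cell table from Matrix Market sidecar files
#'
#' Expects the conventional trio — an MTX coordinate file (genes x cells,
#' 1-based indices), a features file (one gene ID per line) and a barcodes
#' file (one cell barcode per line) — plus a metadata CSV keyed by
#' `barcode`. Dimension mismatches between the MTX header and the sidecar
#' files, and barcodes absent from the metadata, are rejected.
#'
#' @param mtx_path,features_path,barcodes_path,metadata_path File paths.
#' @return A [cell_table()].
#' @export
read_cell_table <- function(mtx_path, features_path, barcodes_path, metadata_path) {
  m <- Matrix::readMM(mtx_path)
  features <- readLines(features_path)
  barcodes <- readLines(barcodes_path)
  if (nrow(m) != length(features)) {
    abort(sprintf("MTX declares %d rows but features file has %d entries",
                  nrow(m), length(features)))
  }
  if (ncol(m) != length(barcodes)) {
    abort(sprintf("MTX declares %d columns but barcodes file has %d entries",
                  ncol(m), length(barcodes)))
  }
  dimnames(m) <- list(features, barcodes)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(barcodes, meta$barcode)
  if (length(missing)) {
    abort(sprintf("barcode(s) missing from metadata: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  cell_table(m, meta[meta$barcode %in% barcodes, ])
}

#' Write a cell table as Matrix Market plus sidecars
#'
#' @param cells A [cell_table()].
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`, `metadata.csv`.
#' @return Invisibly, the directory.
#' @export
write_cell_table <- function(cells, dir) {
  stopifnot(inherits(cells, "cell_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cells$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cells$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(cells$counts), file.path(dir, "barcodes.tsv"))
  readr::write_csv(cells$meta, file.path(dir, "metadata.csv"), progress = FALSE)
  invisible(dir)
}

#' Read / write one-gene-per-line DEG lists
#'
#' @param path File path.
#' @return `read_deg_list()`: character vector.
#' @export
read_deg_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @param genes Character vector (or data frame with a `gene` column).
#' @rdname read_deg_list
#' @export
write_deg_list <- function(genes, path) {
  writeLines(as_gene_vector(genes), path)
  invisible(path)
}
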