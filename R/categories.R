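#' Default keyword map for functional gene categories
#'
#' The lowercase name fragments used to curate lipid, immune and synapse
#' gene sets by substring matching on gene-set names.
#'
#' @return Named list: `Lipid`, `Immune`, `Synapse`, each a character
#'   vector of name fragments (stems, so "immun" also matches
#'   "autoimmune").
#' @export
keyword_default_map <- function() {
  list(
    Lipid = c("lipid", "fat", "sterol"),
    Immune = c("inflam", "cytokine", "immun", "neutro", "antigen",
               "leukocyte", "chemotaxis", "lymphocyte", "interleukin",
               "myeloid", "interferon", "chemokine"),
    Synapse = c("synap", "dendri", "neurotrans", "spine"))
}

#' Curate gene categories by keyword-matching gene-set names
#'
#' A gene belongs to a category iff it is a member of at least one gene set
#' whose lowercased name contains at least one of the category's fragments
#' (case-insensitive substring match; matching is on set names, never on
#' gene symbols). A gene may land in several categories.
#'
#' @param sets Named list of gene sets (each a character vector of genes),
#'   e.g. from [read_gmt()] or [make_gene_sets()].
#' @param keywords Named list mapping categories to lowercase fragments;
#'   defaults to [keyword_default_map()].
#' @return Tibble with columns `gene`, `category`, one row per
#'   (gene, category) pair, sorted.
#' @export
#' @examples
#' keyword_curate(list(SYNAPTIC_SIGNALING = c("Grin1", "Dlg4"),
#'                     METABOLISM_OF_RNA = c("Polr2a")))
keyword_curate <- function(sets, keywords = keyword_default_map()) {
  if (length(sets) == 0) return(tibble(gene = character(), category = character()))
  if (is.null(names(sets))) abort("sets must be named")
  if (any(lengths(keywords) == 0)) abort("keyword fragments must be non-empty")
  set_names <- tolower(names(sets))
  rows <- purrr::imap(keywords, function(frags, cat) {
    hit <- Reduce(`|`, lapply(frags, function(f) grepl(f, set_names, fixed = TRUE)))
    genes <- unique(unlist(sets[hit], use.names = FALSE))
    if (length(genes)) tibble(gene = genes, category = cat) else NULL
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(tibble(gene = character(), category = character()))
  dplyr::arrange(dplyr::distinct(out), .data$category, .data$gene)
}

#' Category counts and percentages within a DEG list
#'
#' For each category, the number of DEGs carrying it and that count as a
#' percentage of the whole DEG list (rounded half away from zero).
#'
#' @param degs DEG list (character vector or data frame with `gene`).
#' @param categories Tibble (`gene`, `category`), e.g. from
#'   [keyword_curate()].
#' @return Tibble: `category`, `n`, `total`, `percent`.
#' @export
category_fractions <- function(degs, categories) {
  genes <- unique(as_gene_vector(degs, "degs"))
  if (length(genes) == 0) abort("DEG list is empty")
  stopifnot(all(c("gene", "category") %in% names(categories)))
  hits <- dplyr::distinct(categories[categories$gene %in% genes, c("gene", "category")])
  out <- hits |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::mutate(total = length(genes),
                  percent = round_half_up(100 * .data$n / .data$total))
  # categories present in the map but absent from the DEG list report 0
  missing <- setdiff(unique(categories$category), out$category)
  if (length(missing)) {
    out <- dplyr::bind_rows(out, tibble(category = missing, n = 0L,
                                        total = length(genes), percent = 0))
  }
  dplyr::arrange(out, .data$category)
}

#' Hypergeometric over-representation of gene sets in a DEG list
#'
#' Upper-tail hypergeometric test per set: the probability of observing at
#' least the seen overlap between the DEG list and the set when drawing
#' |DEGs| genes from a universe of `universe_size` containing |set| set
#' members. A lightweight over-representation analysis standing in for
#' full GO enrichment tooling.
#'
#' @param degs DEG list (subset of the universe).
#' @param sets Named list of gene sets (members must lie in the universe).
#' @param universe Character vector of universe genes, or a single integer
#'   universe size (then membership checks are skipped).
#' @param adjust Multiple-testing adjustment across sets: `"none"`
#'   (default) or `"BH"`.
#' @return Tibble: `set`, `set_size`, `overlap`, `p`, and `p_adj` when
#'   `adjust != "none"`.
#' @export
hypergeometric_enrichment <- function(degs, sets, universe,
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  genes <- unique(as_gene_vector(degs, "degs"))
  if (is.numeric(universe) && length(universe) == 1) {
    n_univ <- as.integer(universe)
    if (length(genes) > n_univ) abort("more DEGs than universe genes")
  } else {
    universe <- unique(universe)
    n_univ <- length(universe)
    if (!all(genes %in% universe)) abort("degs must be a subset of the universe")
    bad <- names(sets)[!purrr::map_lgl(sets, ~ all(.x %in% universe))]
    if (length(bad)) {
      abort(sprintf("sets with members outside the universe: %s",
                    paste(bad, collapse = ", ")))
    }
  }
  out <- tibble(
    set = names(sets),
    set_size = unname(lengths(sets)),
    overlap = unname(purrr::map_int(sets, ~ length(intersect(.x, genes)))))
  if (any(out$overlap > pmin(out$set_size, length(genes)))) {
    abort("overlap exceeds min(set size, DEG count)")
  }
  out$p <- stats::phyper(out$overlap - 1, out$set_size,
                         n_univ - out$set_size, length(genes),
                         lower.tail = FALSE)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Simulate a named gene-set collection with planted category structure
#'
#' Allocates a fraction of the gene universe to each planned category,
#' splits each category's genes across sets whose names embed that
#' category's keyword fragment, and puts the remaining genes into
#' neutral sets whose names match no category keyword. The recorded
#' membership is the ground truth for [keyword_curate()].
#'
#' @param genes Character vector, the gene universe (non-empty).
#' @param plan Tibble with columns `category`, `fragment`, `prop`: the
#'   fraction of the universe assigned to sets named with `fragment`.
#'   Props must sum to at most 1; the remainder becomes neutral sets.
#' @param sets_per_category Number of sets per planned category (and for
#'   the neutral remainder). 0 yields an empty collection.
#' @param seed Integer seed.
#' @return List with `sets` (named list of character vectors) and
#'   `membership` (tibble `gene`, `category`; neutral genes get `"none"`).
#' @export
make_gene_sets <- function(genes, plan, sets_per_category = 3, seed = 1L) {
  if (length(genes) == 0) abort("gene universe is empty")
  stopifnot(all(c("category", "fragment", "prop") %in% names(plan)))
  if (sum(plan$prop) > 1 + 1e-9) abort("plan props must sum to at most 1")
  if (sets_per_category == 0) {
    return(list(sets = stats::setNames(list(), character()),
                membership = tibble(gene = character(), category = character())))
  }
  withr::with_seed(seed, {
    props <- c(plan$prop, 1 - sum(plan$prop))
    sizes <- apportion(length(genes), props)
    shuffled <- sample(genes)
    alloc <- split(shuffled, rep(seq_along(sizes), sizes))
    sets <- list()
    membership <- list()
    for (i in seq_len(nrow(plan))) {
      g <- alloc[[as.character(i)]]
      if (is.null(g) || length(g) == 0) next
      bin <- sample(rep_len(seq_len(sets_per_category), length(g)))
      for (k in seq_len(sets_per_category)) {
        members <- g[bin == k]
        if (!length(members)) next
        nm <- sprintf("%s_RELATED_SET_%02d", toupper(plan$fragment[i]), k)
        sets[[nm]] <- sort(members)
      }
      membership[[i]] <- tibble(gene = g, category = plan$category[i])
    }
    rest <- alloc[[as.character(length(sizes))]]
    if (!is.null(rest) && length(rest)) {
      bin <- sample(rep_len(seq_len(sets_per_category), length(rest)))
      for (k in seq_len(sets_per_category)) {
        members <- rest[bin == k]
        if (!length(members)) next
        sets[[sprintf("GENERIC_PROCESS_SET_%02d", k)]] <- sort(members)
      }
      membership <- c(membership, list(tibble(gene = rest, category = "none")))
    }
    list(sets = sets, membership = dplyr::arrange(dplyr::bind_rows(membership),
                                                  .data$gene))
  })
}
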