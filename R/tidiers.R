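#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential expression result
#'
#' @param x A `de_result` from [nb_lrt_test()].
#' @param ... Unused.
#' @return The result as a plain tibble.
#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) {
  as_tibble(unclass(x))
}

#' One-row summary of a differential expression result
#'
#' @param x A `de_result`.
#' @param alpha DEG threshold used for the counts.
#' @param ... Unused.
#' @return Tibble: contrast labels, gene counts, DEG counts up/down.
#' @method glance de_result
#' @export
glance.de_result <- function(x, alpha = 0.01, ...) {
  degs <- x[x$p <= alpha, ]
  tibble(group_a = attr(x, "group_a"), group_b = attr(x, "group_b"),
         n_genes = nrow(x), n_degs = nrow(degs),
         n_up = sum(degs$direction == "up"),
         n_down = sum(degs$direction == "down"))
}

#' Tidy a rescue table
#'
#' @param x A `rescue_table` from [classify_rescue()].
#' @param ... Unused.
#' @return Plain tibble of per-gene labels.
#' @method tidy rescue_table
#' @export
tidy.rescue_table <- function(x, ...) as_tibble(unclass(x))

#' One-row summary of a rescue classification
#'
#' @param x A `rescue_table`.
#' @param ... Unused.
#' @return Tibble with class counts, list sizes and the restored fraction
#'   of the disease-contrast list.
#' @method glance rescue_table
#' @export
glance.rescue_table <- function(x, ...) {
  counts <- table(x$label)
  tibble(restored = as.integer(counts[["Restored"]]),
         maintained = as.integer(counts[["Maintained"]]),
         new = as.integer(counts[["New"]]),
         n_a = attr(x, "n_a"), n_b = attr(x, "n_b"),
         restored_fraction = as.integer(counts[["Restored"]]) / attr(x, "n_a"))
}

#' One-row summary of restoration magnitude
#'
#' @param x A `restoration_summary` from [restoration_magnitude()].
#' @param ... Unused.
#' @return Tibble: `mean_reduction_pct`, `n_genes`, `n_excluded`.
#' @method glance restoration_summary
#' @export
glance.restoration_summary <- function(x, ...) {
  tibble(mean_reduction_pct = attr(x, "mean_reduction_pct"),
         n_genes = nrow(x), n_excluded = attr(x, "n_excluded"))
}

#' Tidy an IEG panel comparison
#'
#' @param x An `ieg_comparison` from [panel_group_comparison()].
#' @param which `"anova"` (default), `"dunnett"` or `"scores"`.
#' @param ... Unused.
#' @return The requested component as a tibble.
#' @method tidy ieg_comparison
#' @export
tidy.ieg_comparison <- function(x, which = c("anova", "dunnett", "scores"), ...) {
  x[[match.arg(which)]]
}

#' One-row summary of an IEG panel comparison
#'
#' @param x An `ieg_comparison`.
#' @param ... Unused.
#' @return Tibble: panel size, interaction p, minimum Dunnett p.
#' @method glance ieg_comparison
#' @export
glance.ieg_comparison <- function(x, ...) {
  inter <- x$anova[x$anova$term == "genotype:treatment", ]
  tibble(n_panel = length(x$panel),
         interaction_p = inter$p.value[1],
         min_dunnett_p = min(x$dunnett$p.value))
}
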