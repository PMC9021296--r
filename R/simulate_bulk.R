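#' Specify a synthetic four-group bulk RNA-seq experiment
#'
#' Describes the simulated study design: four groups (WT-D, 3xTg-D, WT-S,
#' 3xTg-S), negative-binomial counts with `Var = mu + dispersion * mu^2`,
#' and four ground-truth gene classes driving the rescue analysis:
#'
#' * `null` — equal means in all groups;
#' * `restored` — shifted by `effect_log2fc` in 3xTg-D only (the treatment
#'   returns the 3xTg-S mean to the WT-D baseline);
#' * `maintained` — shifted in both 3xTg-D and 3xTg-S;
#' * `new` — shifted in 3xTg-S only.
#'
#' Per-sample library sizes are heterogeneous: size factors are drawn
#' log-normal with standard deviation `libsize_sigma` on the log scale, so
#' normalization is a non-trivial part of any downstream pipeline.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Replicates per group (same for all four groups).
#' @param baseline_mean Expected count for an unshifted gene, before
#'   library-size scaling.
#' @param dispersion Negative-binomial dispersion `alpha` (0 gives Poisson).
#' @param effect_log2fc Magnitude of the genotype/treatment shift in log2
#'   units; each affected gene gets a random sign.
#' @param class_fractions Named proportions over
#'   `c("null", "restored", "maintained", "new")`; must sum to 1.
#' @param libsize_sigma Log-scale SD of the per-sample size factors.
#' @param seed Integer seed; identical specs give bitwise-identical output.
#' @return A `bulk_sim_spec` list, validated.
#' @export
bulk_sim_spec <- function(n_genes = 2000,
                          n_per_group = 4,
                          baseline_mean = 100,
                          dispersion = 0.1,
                          effect_log2fc = 2,
                          class_fractions = c(null = 0.7, restored = 0.1,
                                              maintained = 0.1, new = 0.1),
                          libsize_sigma = 0.2,
                          seed = 1L) {
  if (n_genes < 1 || n_per_group < 1) abort("n_genes and n_per_group must be positive")
  if (baseline_mean <= 0) abort("baseline_mean must be strictly positive")
  if (dispersion < 0) abort("dispersion must be non-negative")
  classes <- c("null", "restored", "maintained", "new")
  if (!setequal(names(class_fractions), classes)) {
    abort("class_fractions must be named null, restored, maintained, new")
  }
  class_fractions <- class_fractions[classes]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-8) {
    abort("class_fractions must be non-negative and sum to 1")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
         baseline_mean = baseline_mean, dispersion = dispersion,
         effect_log2fc = effect_log2fc, class_fractions = class_fractions,
         libsize_sigma = libsize_sigma, seed = as.integer(seed)),
    class = "bulk_sim_spec")
}

# largest-remainder apportionment of n items over fractions p (sums to n)
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a four-group bulk count matrix with ground truth
#'
#' Draws gene-by-sample negative-binomial counts under the design in
#' [bulk_sim_spec()] and returns the counts, the sample sheet and a truth
#' table recording every gene's class and per-group means.
#'
#' @param spec A [bulk_sim_spec()].
#' @return A list of class `bulk_sim` with elements
#'   `counts` (tibble: `gene` plus one column per sample),
#'   `design` (tibble: `sample_id`, `genotype`, `treatment`),
#'   `truth` (tibble: `gene`, `class`, `sign`, one mean column per group),
#'   `size_factors` (tibble: `sample_id`, `size_factor` — the true factors).
#' @export
#' @examples
#' sim <- simulate_bulk_counts(bulk_sim_spec(n_genes = 50, seed = 7))
#' dplyr::count(sim$truth, class)
simulate_bulk_counts <- function(spec) {
  stopifnot(inherits(spec, "bulk_sim_spec"))
  groups <- study_groups()
  n <- spec$n_per_group
  design <- tibble(
    sample_id = paste0(rep(gsub("-", "_", groups), each = n), "_", seq_len(n)),
    genotype = rep(sub("-.*", "", groups), each = n),
    treatment = rep(sub(".*-", "", groups), each = n))

  withr::with_seed(spec$seed, {
    counts_class <- apportion(spec$n_genes, spec$class_fractions)
    class <- sample(rep(names(spec$class_fractions), counts_class))
    sign <- sample(c(-1, 1), spec$n_genes, replace = TRUE)
    shift <- 2^(sign * spec$effect_log2fc)

    mu <- matrix(spec$baseline_mean, spec$n_genes, 4,
                 dimnames = list(NULL, groups))
    mu[class == "restored", "3xTg-D"] <- spec$baseline_mean * shift[class == "restored"]
    mu[class == "maintained", "3xTg-D"] <- spec$baseline_mean * shift[class == "maintained"]
    mu[class == "maintained", "3xTg-S"] <- spec$baseline_mean * shift[class == "maintained"]
    mu[class == "new", "3xTg-S"] <- spec$baseline_mean * shift[class == "new"]

    sf <- exp(stats::rnorm(nrow(design), 0, spec$libsize_sigma))
    grp_idx <- match(design_group(design), groups)
    mu_samples <- mu[, grp_idx, drop = FALSE] %*% diag(sf)

    y <- if (spec$dispersion <= 1e-12) {
      matrix(stats::rpois(length(mu_samples), mu_samples), nrow(mu_samples))
    } else {
      matrix(stats::rnbinom(length(mu_samples), mu = mu_samples,
                            size = 1 / spec$dispersion), nrow(mu_samples))
    }
    gene <- sprintf("gene%05d", seq_len(spec$n_genes))
    dimnames(y) <- list(gene, design$sample_id)

    truth <- tibble(gene = gene, class = class, sign = ifelse(class == "null", 0, sign))
    for (g in groups) truth[[paste0("mean_", g)]] <- mu[, g]

    structure(
      list(counts = matrix_to_counts(y), design = design, truth = truth,
           size_factors = tibble(sample_id = design$sample_id, size_factor = sf),
           spec = spec),
      class = "bulk_sim")
  })
}
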