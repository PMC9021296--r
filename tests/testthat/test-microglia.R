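make_qc_cells <- function() {
  meta <- tibble::tibble(
    barcode = sprintf("c%d", 1:5),
    group = "WT-D", cluster = "microglia", subcluster = "RH1",
    umi_count = c(999, 1000, 5000, 2000, 1500),
    mito_fraction = c(0.05, 0.05, 0.27, 0.271, 0.1))
  counts <- Matrix::Matrix(1, nrow = 2, ncol = 5, sparse = TRUE,
                           dimnames = list(c("g1", "g2"), meta$barcode))
  cell_table(counts, meta)
}

test_that("QC thresholds are inclusive on the keep side", {
  f <- qc_filter_cells(make_qc_cells(), quiet = TRUE)
  kept <- f$meta$barcode
  expect_false("c1" %in% kept)  # umi 999 removed
  expect_true("c2" %in% kept)   # umi 1000 kept
  expect_true("c3" %in% kept)   # mito 0.27 kept
  expect_false("c4" %in% kept)  # mito 0.271 removed
  rem <- attr(f, "removed")
  expect_equal(rem$low_umi, 1)
  expect_equal(rem$high_mito, 1)
  expect_equal(rem$total_removed, 2)
})

test_that("QC filtering is idempotent and returns a subset", {
  cells <- simulate_cell_table(cell_sim_spec(
    n_cells_per_group = c("WT-D" = 300), seed = 41))$cells
  f1 <- qc_filter_cells(cells, quiet = TRUE)
  expect_true(all(f1$meta$barcode %in% cells$meta$barcode))
  f2 <- qc_filter_cells(f1, quiet = TRUE)
  expect_identical(f1$meta, f2$meta)
  expect_equal(attr(f2, "removed")$total_removed, 0)
  # empty input passes through
  empty <- cell_table(cells$counts[, 0, drop = FALSE], cells$meta[0, ])
  f0 <- qc_filter_cells(empty, quiet = TRUE)
  expect_equal(ncol(f0$counts), 0)
  expect_equal(attr(f0, "removed")$total_removed, 0)
})

test_that("subcluster proportions sum to 100 per group and errors name empty groups", {
  sim <- simulate_cell_table(cell_sim_spec(seed = 37))
  pr <- subcluster_proportions(sim$cells)
  sums <- tapply(pr$percent, pr$group, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # a group whose microglia were all relabeled errors by name
  cells <- sim$cells
  cells$meta$cluster[cells$meta$group == "WT-S"] <- "neuron"
  expect_error(subcluster_proportions(cells), "WT-S")
})

test_that("activation scores follow the defining ratio and printed-arithmetic examples", {
  tab <- tibble::tibble(
    group = "WT-D",
    subcluster = microglia_subclusters(),
    n = c(28, 15, 27, 19, 2, 2, 7) * 10)
  sc <- activation_score(tab)
  expect_equal(sc$score[sc$lineage == "AR/AIR"], (27 + 2 + 2) / 43 * 100,
               tolerance = 1e-12)  # ~72.1
  expect_equal(sc$score[sc$lineage == "ASR"], (19 + 7) / 43 * 100,
               tolerance = 1e-12)  # ~60.5
  expect_equal(round(sc$score, 1), c(72.1, 60.5))
})

test_that("activation score is scale-invariant: counts, percentages and cells agree", {
  tab <- tibble::tibble(group = rep(c("WT-D", "3xTg-D"), each = 7),
                        subcluster = rep(microglia_subclusters(), 2),
                        n = c(30, 13, 27, 19, 2, 2, 7,
                              15, 8, 30, 20, 10, 7, 10))
  from_counts <- activation_score(tab)
  pct <- tab |>
    dplyr::group_by(group) |>
    dplyr::mutate(percent = 100 * n / sum(n), n = NULL) |>
    dplyr::ungroup()
  from_pct <- activation_score(pct)
  expect_equal(from_counts$score, from_pct$score, tolerance = 1e-12)
  cells <- cells_from_counts(tab)
  from_cells <- activation_score(cells)
  expect_equal(dplyr::arrange(from_cells, group, lineage)$score,
               dplyr::arrange(from_counts, group, lineage)$score,
               tolerance = 1e-12)
})

test_that("activation score errors on zero resting cells and overlapping lineage maps", {
  tab <- tibble::tibble(group = "G", subcluster = microglia_subclusters(),
                        n = c(0, 0, 10, 10, 5, 5, 5))
  expect_error(activation_score(tab), "zero resting")
  lm <- lineage_default_map()
  lm$lineages$`AR/AIR` <- c(lm$lineages$`AR/AIR`, "RH1")
  tab$n <- c(5, 5, 10, 10, 5, 5, 5)
  expect_error(activation_score(tab, lineage_map = lm), "disjoint")
})

test_that("activation score is stable under uniform subsampling", {
  sim <- simulate_cell_table(cell_sim_spec(
    n_cells_per_group = c("WT-D" = 10000), seed = 55))
  full <- activation_score(sim$cells)
  set.seed(56)
  keep <- sample(ncol(sim$cells$counts), 5000)
  subs <- cell_table(sim$cells$counts[, keep], sim$cells$meta[keep, ])
  half <- activation_score(subs)
  expect_equal(half$score, full$score, tolerance = 0.05 * max(full$score))
})

test_that("rank-sum p-values match exhaustive enumeration on small groups", {
  # fixed 3v3 separated case: only the 2 extreme assignments reach |W - E|
  p <- degrescue:::rank_sum_p(c(1, 2, 3), c(4, 5, 6))
  expect_equal(p, 2 / 20)
  set.seed(610)
  for (i in 1:25) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- sample(0:5, n1, replace = TRUE)   # heavy ties
    b <- sample(0:5, n2, replace = TRUE)
    expect_equal(degrescue:::rank_sum_p(a, b), enum_rank_sum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum agrees with wilcox.test exact p on tie-free data", {
  set.seed(611)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(7)
    expect_equal(degrescue:::rank_sum_p(a, b),
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation is calibrated on a null cluster", {
  # two groups drawn from the same multinomial profile
  spec <- cell_sim_spec(
    n_cells_per_group = c("WT-D" = 200, "3xTg-D" = 200),
    subcluster_proportions = default_subcluster_proportions()[
      c("WT-D", "WT-D"), ] |> `rownames<-`(c("WT-D", "3xTg-D")),
    n_genes = 300, seed = 62)
  sim <- simulate_cell_table(spec)
  mk <- cluster_markers(sim$cells, "WT-D", "3xTg-D")
  frac <- mean(mk$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("marker detection recovers an injected MHC-I-like shift and only that", {
  # identical composition in both groups; five named genes shifted in B
  # a large background universe keeps the compositional side-effect of the
  # shift (multinomial proportions must sum to 1) below detectability
  genes <- c("H2-D1", "H2-K1", "H2-T23", "H2-Q6", "H2-M3",
             sprintf("bg%03d", 1:495))
  set.seed(63)
  n <- 150
  base <- rgamma(length(genes), 0.8) + 0.1
  draw <- function(shift) {
    w <- base
    w[1:5] <- w[1:5] * shift
    sapply(seq_len(n), function(i) rmultinom(1, 3000, w))
  }
  mA <- draw(1); mB <- draw(4)
  counts <- cbind(mA, mB)
  dimnames(counts) <- list(genes, sprintf("c%04d", seq_len(2 * n)))
  meta <- tibble::tibble(barcode = colnames(counts),
                         group = rep(c("WT-D", "3xTg-D"), each = n),
                         cluster = "microglia", subcluster = "RH1",
                         umi_count = colSums(counts), mito_fraction = 0.05)
  mk <- cluster_markers(cell_table(counts, meta), "WT-D", "3xTg-D")
  sig <- mk$gene[mk$significant]
  expect_setequal(sig, c("H2-D1", "H2-K1", "H2-T23", "H2-Q6", "H2-M3"))
  expect_true(all(mk$log_fc[mk$gene %in% sig] > 0))
})

test_that("marker rescue classification delegates to the Venn rules", {
  mk_ab <- tibble::tibble(gene = sprintf("g%03d", 1:122),
                          p_adj = 0.01)
  mk_as <- tibble::tibble(gene = c(sprintf("g%03d", 31:122),
                                   sprintf("n%02d", 1:34)),
                          p_adj = 0.01)
  r <- rescue_classify_markers(mk_ab, mk_as)
  expect_equal(sum(r$label == "Restored"), 30)
  expect_equal(sum(r$label == "Maintained"), 92)
  expect_equal(sum(r$label == "New"), 34)
  # identical lists -> all Maintained; disjoint -> all Restored/New
  r2 <- rescue_classify_markers(mk_ab, mk_ab)
  expect_true(all(r2$label == "Maintained"))
})

test_that("cluster_markers validates cluster and group sizes", {
  sim <- simulate_cell_table(cell_sim_spec(
    n_cells_per_group = c("WT-D" = 20, "3xTg-D" = 2), seed = 65))
  expect_error(cluster_markers(sim$cells, "WT-D", "3xTg-D", cluster = "astro"),
               "not present")
  expect_error(cluster_markers(sim$cells, "WT-D", "3xTg-D"), "at least 3")
})
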