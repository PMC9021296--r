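test_that("rescue classification satisfies the Venn identities on random lists", {
  set.seed(301)
  universe <- sprintf("g%04d", 1:500)
  for (i in 1:20) {
    a <- sample(universe, sample(0:200, 1))
    b <- sample(universe, sample(1:200, 1))
    if (length(a) == 0) a <- sample(universe, 1)
    r <- classify_rescue(a, b)
    counts <- table(r$label)
    expect_equal(unname(counts[["Restored"]]) + unname(counts[["Maintained"]]),
                 length(a))
    expect_equal(unname(counts[["Maintained"]]) + unname(counts[["New"]]),
                 length(b))
    expect_equal(anyDuplicated(r$gene), 0)
    expect_setequal(r$gene, union(a, b))
    expect_setequal(r$gene[r$label == "Maintained"], intersect(a, b))
  }
})

test_that("rescue classification handles degenerate and invalid inputs", {
  r <- classify_rescue(c("a", "b"), c("a", "b"))
  expect_true(all(r$label == "Maintained"))
  r2 <- classify_rescue(c("a", "b", "c"), c("d", "e", "f", "g", "h"))
  expect_equal(sum(r2$label == "Restored"), 3)
  expect_equal(sum(r2$label == "Maintained"), 0)
  expect_equal(sum(r2$label == "New"), 5)
  expect_error(classify_rescue(c("a", "a"), "b"), "duplicate")
})

test_that("rescue classification is equivariant under gene relabeling", {
  set.seed(302)
  a <- sprintf("g%03d", sample(100, 40))
  b <- sprintf("g%03d", sample(100, 60))
  r1 <- classify_rescue(a, b)
  relabel <- setNames(sprintf("X%03d", sample(100)), sprintf("g%03d", 1:100))
  r2 <- classify_rescue(unname(relabel[a]), unname(relabel[b]))
  m1 <- setNames(as.character(r1$label), unname(relabel[r1$gene]))
  m2 <- setNames(as.character(r2$label), r2$gene)
  expect_mapequal(as.list(m1), as.list(m2))
})

test_that("signed mode splits direction-flipping genes into Restored and New", {
  a <- tibble::tibble(gene = c("g1", "g2"), direction = c("up", "down"))
  b <- tibble::tibble(gene = c("g1", "g2"), direction = c("up", "up"))
  r <- classify_rescue(a, b, signed = TRUE)
  expect_equal(sort(as.character(r$label[r$gene == "g2"])), c("New", "Restored"))
  expect_equal(as.character(r$label[r$gene == "g1"]), "Maintained")
})

test_that("restoration magnitude matches the defining arithmetic", {
  # one gene: control mean 1, disease 3, treated 2 on the log2(x+1) scale
  # choose normalized values so log2(mean+1) hits exactly 1, 3, 2
  vals <- c(2^1 - 1, 2^3 - 1, 2^2 - 1, 2^1 - 1)  # WT-D, 3xTg-D, 3xTg-S, WT-S
  m <- matrix(rep(vals, each = 2), nrow = 1,
              dimnames = list("g1", c("WT_D_1", "WT_D_2", "TG_D_1", "TG_D_2",
                                      "TG_S_1", "TG_S_2", "WT_S_1", "WT_S_2")))
  design <- tibble::tibble(
    sample_id = colnames(m),
    genotype = c("WT", "WT", "3xTg", "3xTg", "3xTg", "3xTg", "WT", "WT"),
    treatment = c("D", "D", "D", "D", "S", "S", "S", "S"))
  rm <- restoration_magnitude(expr_tibble(m), design, "g1")
  expect_equal(rm$reduction_pct, 50)

  # full restoration -> 100; no restoration -> 0
  m2 <- m; m2[1, c("TG_S_1", "TG_S_2")] <- 2^1 - 1
  expect_equal(restoration_magnitude(expr_tibble(m2), design, "g1")$reduction_pct, 100)
  m3 <- m; m3[1, c("TG_S_1", "TG_S_2")] <- 2^3 - 1
  expect_equal(restoration_magnitude(expr_tibble(m3), design, "g1")$reduction_pct, 0)

  expect_error(restoration_magnitude(expr_tibble(m), design, character()), "empty")
})

test_that("restoration magnitude equals 100 minus 100x the residual ratio for every gene", {
  sim <- simulate_bulk_counts(bulk_sim_spec(n_genes = 120, seed = 71))
  norm <- normalize_counts(sim$counts, size_factors(sim$counts))
  genes <- sim$counts$gene[1:50]
  rm <- restoration_magnitude(norm, sim$design, genes)
  y <- as.matrix(norm[-1]); rownames(y) <- norm$gene
  grp <- paste(sim$design$genotype, sim$design$treatment, sep = "-")
  lg <- function(g) log2(rowMeans(y[genes, grp == g, drop = FALSE]) + 1)
  resid <- abs(lg("3xTg-S") - lg("WT-D")) / abs(lg("3xTg-D") - lg("WT-D"))
  ok <- !rm$excluded
  expect_equal(rm$reduction_pct[ok], (100 - 100 * resid)[ok], ignore_attr = TRUE)
})

test_that("near-constant genes are excluded from the restoration mean", {
  m <- matrix(c(5, 5, 5, 5, 7, 7, 5, 5), nrow = 1,
              dimnames = list("g1", c("WT_D_1", "WT_D_2", "TG_D_1", "TG_D_2",
                                      "TG_S_1", "TG_S_2", "WT_S_1", "WT_S_2")))
  design <- tibble::tibble(
    sample_id = colnames(m),
    genotype = c("WT", "WT", "3xTg", "3xTg", "3xTg", "3xTg", "WT", "WT"),
    treatment = c("D", "D", "D", "D", "S", "S", "S", "S"))
  rm <- restoration_magnitude(expr_tibble(m), design, "g1")
  expect_true(rm$excluded[1])
  expect_equal(attr(rm, "n_excluded"), 1)
})

test_that("category rescue statistics reproduce printed worked examples", {
  # synapse: 142 disease-contrast DEGs, 56 restored -> 39%
  a <- sprintf("syn%03d", 1:142)
  b <- c(a[57:142], sprintf("new%03d", 1:142))
  r <- classify_rescue(a, b)
  cats <- tibble::tibble(gene = c(a, sprintf("new%03d", 1:142)),
                         category = "Synapse")
  st <- category_rescue_stats(r, cats)
  expect_equal(st$restored, 56)
  expect_equal(st$a_degs, 142)
  expect_equal(st$restored_pct, 39)
  expect_equal(st$new, 142)
})

test_that("categories with zero disease-contrast DEGs report NA percent", {
  r <- classify_rescue(c("a"), c("a", "b"))
  st <- category_rescue_stats(r, tibble::tibble(gene = "b", category = "Lipid"))
  expect_true(is.na(st$restored_pct[st$category == "Lipid"]))
})

test_that("multi-list overlap returns membership, consensus and pairwise counts", {
  five <- list(
    `3xTg` = c("Abcd2", "Bank1", "Ccl6", "Ctsl", "Fam102b", "Filip1l",
               "H2-D1", "H2-K1", "Nrp1", "Pnp", "Rplp1", "Rps13", "Apoe", "Trem2"),
    `5xFAD` = c("Abcd2", "Bank1", "Ccl6", "Ctsl", "Fam102b", "Filip1l",
                "H2-D1", "H2-K1", "Nrp1", "Pnp", "Rplp1", "Rps13", "Cst7"),
    `APP-SAA` = c("Abcd2", "Bank1", "Ccl6", "Ctsl", "Fam102b", "Filip1l",
                  "H2-D1", "H2-K1", "Nrp1", "Pnp", "Rplp1", "Rps13", "Itgax"),
    `AppNLGF` = c("Abcd2", "Bank1", "Ccl6", "Ctsl", "Fam102b", "Filip1l",
                  "H2-D1", "H2-K1", "Nrp1", "Pnp", "Rplp1", "Rps13", "Clec7a"),
    `APP-PS1` = c("Abcd2", "Bank1", "Ccl6", "Ctsl", "Fam102b", "Filip1l",
                  "H2-D1", "H2-K1", "Nrp1", "Pnp", "Rplp1", "Rps13", "Tyrobp"))
  ov <- multi_list_overlap(five)
  expect_setequal(ov$consensus,
                  c("Abcd2", "Bank1", "Ccl6", "Ctsl", "Fam102b", "Filip1l",
                    "H2-D1", "H2-K1", "Nrp1", "Pnp", "Rplp1", "Rps13"))
  expect_length(ov$consensus, 12)
  # consensus genes are present in every list
  mem <- ov$membership[ov$membership$gene %in% ov$consensus, ]
  expect_true(all(as.matrix(mem[names(five)])))
  expect_equal(unname(ov$pairwise["3xTg", "5xFAD"]), 12)

  two <- multi_list_overlap(list(x = c("a", "b"), y = c("a", "b")))
  expect_setequal(two$consensus, c("a", "b"))
  expect_error(multi_list_overlap(list(x = c("a"))), "at least 2")
})
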