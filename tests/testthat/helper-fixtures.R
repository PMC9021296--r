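# Shared fixtures built in code.

# small four-group count table with hand-set values
toy_counts <- function() {
  tibble::tibble(
    gene = c("g1", "g2", "g3"),
    WT_D_1 = c(10L, 50L, 100L), WT_D_2 = c(12L, 55L, 110L),
    TG_D_1 = c(100L, 52L, 95L), TG_D_2 = c(110L, 48L, 105L))
}

toy_design <- function() {
  tibble::tibble(
    sample_id = c("WT_D_1", "WT_D_2", "TG_D_1", "TG_D_2"),
    genotype = c("WT", "WT", "3xTg", "3xTg"),
    treatment = "D")
}

# design with unit-variance four-group layout, n per group
four_group_design <- function(n) {
  groups <- study_groups()
  tibble::tibble(
    sample_id = paste0(rep(gsub("-", "_", groups), each = n), "_", seq_len(n)),
    genotype = rep(sub("-.*", "", groups), each = n),
    treatment = rep(sub(".*-", "", groups), each = n))
}

# expression tibble from a genes x samples matrix
expr_tibble <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                   tibble::as_tibble(as.data.frame(m)))
}

# brute-force NB likelihood maximization over a mean grid (oracle for the
# LRT optimizer); alpha fixed per gene, offsets sf
grid_nb_loglik <- function(y, sf, alpha) {
  obj <- function(q) sum(stats::dnbinom(y, size = 1 / alpha, mu = q * sf, log = TRUE))
  q0 <- sum(y) / sum(sf)
  if (q0 == 0) return(obj(0))
  grid <- q0 * exp(seq(-2, 2, length.out = 2001))
  vals <- vapply(grid, obj, numeric(1))
  best <- grid[which.max(vals)]
  fine <- best * exp(seq(-0.01, 0.01, length.out = 2001))
  max(vapply(fine, obj, numeric(1)))
}

grid_lrt_p <- function(yA, yB, sfA, sfB, alpha) {
  ll_alt <- grid_nb_loglik(yA, sfA, alpha) + grid_nb_loglik(yB, sfB, alpha)
  ll_null <- grid_nb_loglik(c(yA, yB), c(sfA, sfB), alpha)
  stat <- max(2 * (ll_alt - ll_null), 0)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# exhaustive-enumeration two-sided rank-sum oracle: recompute the statistic
# from the raw values for every assignment of group labels
enum_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  e <- n1 * (n + 1) / 2
  obs <- sum(rank(pooled)[seq_len(n1)])
  idx <- utils::combn(n, n1)
  stats <- apply(idx, 2, function(i) sum(rank(pooled)[i]))
  mean(abs(stats - e) >= abs(obs - e) - 1e-9)
}

# cell table built directly from per-group subcluster counts (one cell per
# count unit, minimal 1-gene matrix)
cells_from_counts <- function(tab) {
  # tab: tibble(group, subcluster, n)
  meta <- tab[rep(seq_len(nrow(tab)), tab$n), c("group", "subcluster")]
  meta$barcode <- sprintf("c%05d", seq_len(nrow(meta)))
  meta$cluster <- "microglia"
  meta$umi_count <- 2000
  meta$mito_fraction <- 0.05
  counts <- Matrix::Matrix(1, nrow = 1, ncol = nrow(meta), sparse = TRUE,
                           dimnames = list("g1", meta$barcode))
  cell_table(counts, meta)
}
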