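test_that("the MAF matrix uses the subset-wise minor allele and mean imputation", {
  # ref freqs (0.9, 0.8): minor allele is alt -> row values 0.1, 0.2
  tab <- freq_table_from(cbind(c(0.9, 0.2), c(0.8, 0.4)), depth = 10L)
  maf <- build_maf_matrix(tab)
  expect_equal(unname(maf[, 1]), c(0.1, 0.2))
  # ref mean 0.3 < 0.5: minor allele is ref, values kept as-is
  expect_equal(unname(maf[, 2]), c(0.2, 0.4))
  expect_true(all(maf >= 0 & maf <= 1))

  # one undefined cell among (0.2, NA, 0.4) imputes the mean 0.3
  tab3 <- freq_table_from(matrix(c(0.2, 0.3, 0.4), nrow = 1), depth = 10L)
  tab3$ref_depth[1, 2] <- 0L; tab3$alt_depth[1, 2] <- 0L
  tab3 <- pool_freq_table(tab3$snps, tab3$pools, tab3$ref_depth, tab3$alt_depth)
  maf3 <- build_maf_matrix(tab3)
  expect_equal(unname(maf3[2, 1]), 0.3)
  # a SNP undefined in every subset pool is dropped with a warning
  tab4 <- freq_table_from(cbind(c(0.2, 0.5), c(0.4, 0.5)), depth = 10L)
  tab4$ref_depth[1, ] <- 0L; tab4$alt_depth[1, ] <- 0L
  tab4 <- pool_freq_table(tab4$snps, tab4$pools, tab4$ref_depth, tab4$alt_depth)
  expect_warning(m4 <- build_maf_matrix(tab4), "dropped")
  expect_equal(ncol(m4), 1L)
})

test_that("scaled PCA eigenvalues sum to the retained column count", {
  set.seed(11)
  x <- matrix(runif(8 * 40), nrow = 8)
  colnames(x) <- paste0("snp", 1:40)
  pc <- run_pca(x)
  expect_equal(sum(pc$eigenvalues), 40, tolerance = 1e-6)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))  # non-increasing
  expect_true(all(pc$eigenvalues >= -1e-12))
  # two identical pools: degenerate beyond the first axis
  y <- rbind(x[1, ], x[1, ])
  expect_error(run_pca(y[1, , drop = FALSE]), "at least 2 pools")
})

test_that("PC1 separates two planted pool clusters with opposite signs", {
  set.seed(21)
  base <- runif(100, 0.3, 0.7)
  shift <- c(-0.25, -0.25, 0.25, 0.25)
  x <- t(sapply(shift, function(s) pmin(pmax(base + s, 0), 1))) +
    matrix(rnorm(4 * 100, sd = 0.01), nrow = 4)
  colnames(x) <- paste0("snp", seq_len(ncol(x)))
  pc <- run_pca(x)
  s1 <- pc$scores[, 1]
  expect_equal(sign(s1[1]), sign(s1[2]))
  expect_equal(sign(s1[3]), sign(s1[4]))
  expect_true(sign(s1[1]) != sign(s1[3]))
})

test_that("significant PCs follow the above-average eigenvalue rule", {
  expect_equal(significant_pcs(list(eigenvalues = c(4, 0, 0, 0))), 1L)
  expect_equal(significant_pcs(list(eigenvalues = c(3, 2, 0.5, 0.5))), c(1L, 2L))
  # all-equal eigenvalues: nothing beats the mean, fall back to PC1
  expect_equal(significant_pcs(list(eigenvalues = c(2, 2, 2))), 1L)
})

test_that("per-PC contributions are normalized and reward informative SNPs", {
  set.seed(31)
  x <- matrix(runif(6 * 30), nrow = 6)
  colnames(x) <- paste0("snp", 1:30)
  pc <- run_pca(x)
  ctr <- sweep(pc$coord^2, 2, pc$eigenvalues, `/`) * 100
  live <- pc$eigenvalues > 1e-10
  expect_true(all(abs(colSums(ctr[, live, drop = FALSE]) - 100) < 1e-6))
  # constant SNP scores 0; the only varying SNP takes the full 100
  toy <- cbind(snpA = c(0.1, 0.2, 0.8, 0.9), snpB = rep(0.3, 4))
  pct <- run_pca(toy)
  sc <- snp_contribution(pct, pcs = 1L)
  expect_equal(unname(sc["snpA"]), 100)
  expect_equal(unname(sc["snpB"]), 0)
  expect_error(snp_contribution(pc, pcs = 99L), "out of range")
})

test_that("hierarchical selection honours quotas, dedup and determinism", {
  cfg <- toy_config(n_snps = 300L, n_ind = 2L)
  sim <- simulate_dataset(cfg, seed = 14)
  pan <- hierarchical_pca_select(sim$pool_table, cfg)
  expect_equal(nrow(pan), 20L + 10L + 10L)
  expect_equal(anyDuplicated(paste(pan$chrom, pan$pos)), 0L)
  expect_equal(sum(pan$source == "pca_global"), 20L)
  expect_equal(sum(pan$source == "pca_L1"), 10L)
  # all-zero quotas: empty selection
  empty <- hierarchical_pca_select(sim$pool_table, cfg,
                                   quotas = list(global = 0L, L1 = 0L, L2 = 0L))
  expect_equal(nrow(empty), 0L)
  # determinism
  pan2 <- hierarchical_pca_select(sim$pool_table, cfg)
  expect_identical(as.data.frame(pan), as.data.frame(pan2))
  # shortfall error
  expect_error(
    hierarchical_pca_select(sim$pool_table, cfg,
                            quotas = list(global = 10000L, L1 = 0L, L2 = 0L)),
    "quota")
})

test_that("planted lineage AIMs are recovered at the global level", {
  cfg <- honeybee_hierarchy(f_lineage = 0.02, f_subspecies = 0.01,
                            f_pool = 0.01, n_snps = 1050L,
                            n_individuals_per_pool = 2L, pool_coverage = 100,
                            quotas = list(global = 50L, A = 0L, C = 0L,
                                          M = 0L, O = 0L))
  sim <- simulate_dataset(cfg, seed = 1, plant = list(n = 50L, gap = 0.8))
  pan <- hierarchical_pca_select(sim$pool_table, cfg)
  ids <- paste(sim$pool_table$snps$chrom, sim$pool_table$snps$pos, sep = ":")
  planted_ids <- ids[sim$truth$planted]
  recovered <- sum(paste(pan$chrom, pan$pos, sep = ":") %in% planted_ids)
  expect_gte(recovered, 45L)  # >= 90% of the 50 planted
})

test_that("two-branch panel merge is duplicate-free and additive", {
  cfg <- toy_config(n_snps = 400L, n_ind = 2L)
  sim <- simulate_dataset(cfg, seed = 15)
  pan <- build_panel(sim$pool_table, cfg, k_loose = 3L, k_stringent = 7L)
  expect_equal(nrow(pan), (20L + 10L + 10L) + 4L * 10L)
  expect_equal(anyDuplicated(paste(pan$chrom, pan$pos)), 0L)
  # FST-first merge order also yields the additive total
  pan2 <- build_panel(sim$pool_table, cfg, k_loose = 3L, k_stringent = 7L,
                      fst_first = TRUE)
  expect_equal(nrow(pan2), nrow(pan))
})
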