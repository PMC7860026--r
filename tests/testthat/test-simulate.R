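test_that("Balding-Nichols drift is unbiased with variance F p (1-p)", {
  set.seed(1)
  x <- drift_freqs(rep(0.5, 1e5), F = 0.1)
  expect_lt(abs(mean(x) - 0.5), 0.005)          # E[child] = p
  expect_lt(abs(var(x) - 0.025) / 0.025, 0.10)  # Var = F p (1-p) = 0.025
  expect_true(all(x >= 0 & x <= 1))
  # near-zero F: child hugs parent
  y <- drift_freqs(rep(0.3, 1000), F = 1e-4)
  expect_lt(max(abs(y - 0.3)), 0.05)
  # fixed parents stay fixed
  expect_equal(drift_freqs(c(0, 1), F = 0.2), c(0, 1))
  expect_error(drift_freqs(0.5, F = 1.2), "F must")
})

test_that("simulate_dataset is bit-reproducible and respects its config", {
  cfg <- toy_config(n_snps = 120L, n_ind = 3L)
  a <- simulate_dataset(cfg, seed = 42)
  b <- simulate_dataset(cfg, seed = 42)
  expect_identical(a$pool_table$ref_depth, b$pool_table$ref_depth)
  expect_identical(a$genotypes$g, b$genotypes$g)
  expect_identical(a$truth$pool_freq, b$truth$pool_freq)
  c <- simulate_dataset(cfg, seed = 43)
  expect_false(identical(a$pool_table$ref_depth, c$pool_table$ref_depth))

  expect_equal(dim(a$genotypes$g), c(12L, 120L))
  expect_true(all(a$truth$pool_freq >= 0 & a$truth$pool_freq <= 1))
  expect_true(all(a$pool_table$ref_depth >= 0))
  expect_equal(a$labels$pool_id, rep(cfg$pools, each = 3L))
})

test_that("with vanishing drift all pools track the ancestral frequency", {
  tree <- data.frame(pool = "p1", subspecies = "s1", lineage = "L1")
  cfg <- hierarchy_config(tree, f_lineage = 1e-4, f_subspecies = 1e-4,
                          f_pool = 1e-4, n_snps = 2000L,
                          ancestral_freq_range = c(0.499, 0.501),
                          n_individuals_per_pool = 30L,
                          pool_coverage = 200, null_allele_rate = 0)
  sim <- simulate_dataset(cfg, seed = 2)
  expect_lt(max(abs(sim$truth$pool_freq - 0.5)), 0.05)
  expect_lt(abs(mean(sim$genotypes$g) - 1.0), 0.02)
})

test_that("individuals drawn from frequencies follow Hardy-Weinberg", {
  gm <- sample_individuals_from_freqs(matrix(0.5, nrow = 1), n = 1e4, seed = 9)
  tab <- table(gm$g) / length(gm$g)
  expect_lt(abs(tab[["0"]] - 0.25), 0.02)
  expect_lt(abs(tab[["1"]] - 0.50), 0.02)
  expect_lt(abs(tab[["2"]] - 0.25), 0.02)
  # degenerate frequencies
  g1 <- sample_individuals_from_freqs(matrix(1, nrow = 3), n = 5, seed = 1)
  expect_true(all(g1$g == 2L))
  g0 <- sample_individuals_from_freqs(matrix(0, nrow = 3), n = 5, seed = 1)
  expect_true(all(g0$g == 0L))
})

test_that("zero-depth pool cells become missing genotypes", {
  freqs <- matrix(c(1, 0.5), ncol = 1)
  tab <- freq_table_from(freqs, depth = 10L)
  tab$ref_depth[2, 1] <- 0L
  tab$alt_depth[2, 1] <- 0L
  tab <- pool_freq_table(tab$snps, tab$pools, tab$ref_depth, tab$alt_depth)
  gm <- sample_individuals_from_freqs(tab, n = 4, seed = 3)
  expect_true(all(is.na(gm$g[, 2])))
  expect_true(all(!is.na(gm$g[, 1])))
})

test_that("null-allele masking blanks exactly the masked subspecies cells", {
  gm <- separable_genotypes(n_per_class = 5L, n_snps = 8L)
  ids <- paste(gm$snps$chrom, gm$snps$pos, sep = ":")
  mask <- matrix(FALSE, 2, 8, dimnames = list(c("clsA", "clsB"), ids))
  expect_identical(apply_null_alleles(gm, mask)$g, gm$g)
  mask["clsA", 3] <- TRUE
  out <- apply_null_alleles(gm, mask)
  expect_true(all(is.na(out$g[1:5, 3])))
  expect_identical(out$g[6:10, ], gm$g[6:10, ])
  expect_identical(out$g[, -3], gm$g[, -3])
  mask[] <- TRUE
  expect_true(all(is.na(apply_null_alleles(gm, mask)$g)))
  expect_error(apply_null_alleles(gm, mask[, 1:3]), "mask")
})

test_that("null-allele rate sets the expected call rate for the subspecies", {
  cfg <- hierarchy_config(toy_tree(), n_snps = 2000L,
                          n_individuals_per_pool = 10L,
                          null_allele_rate = c(s1 = 0.1, s2 = 0, s3 = 0, s4 = 0))
  sim <- simulate_dataset(cfg, seed = 8)
  cr <- call_rate(sim$genotypes)
  expect_lt(abs(cr$per_class[["s1"]] - 0.9), 0.02)
  expect_equal(cr$per_class[["s2"]], 1.0)
})

test_that("drift parameter is recoverable from sibling-pool differentiation", {
  tree <- data.frame(pool = c("a", "b"), subspecies = c("s", "s"),
                     lineage = c("L", "L"))
  cfg <- hierarchy_config(tree, f_pool = 0.02, n_snps = 5000L,
                          n_individuals_per_pool = 2L, pool_coverage = 200)
  sim <- simulate_dataset(cfg, seed = 3)
  f_hat <- estimate_drift_F(sim$truth$pool_freq)
  expect_lt(abs(f_hat - 0.02) / 0.02, 0.20)
})

test_that("differentiation decreases down the hierarchy", {
  cfg <- honeybee_hierarchy(n_snps = 5000L, n_individuals_per_pool = 2L)
  sim <- simulate_dataset(cfg, seed = 9)
  pf <- sim$truth$pool_freq
  tr <- cfg$tree
  pairs <- combn(ncol(pf), 2)
  mf <- apply(pairs, 2, function(jk) {
    mean(pairwise_fst(pf[, jk[1]], pf[, jk[2]]))
  })
  same_lin <- tr$lineage[pairs[1, ]] == tr$lineage[pairs[2, ]]
  same_sub <- tr$subspecies[pairs[1, ]] == tr$subspecies[pairs[2, ]]
  cross_lineage <- mean(mf[!same_lin])
  cross_sub_within_lin <- mean(mf[same_lin & !same_sub])
  within_sub <- mean(mf[same_sub])
  expect_gt(cross_lineage, cross_sub_within_lin)
  expect_gt(cross_sub_within_lin, within_sub)
})
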