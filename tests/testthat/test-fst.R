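test_that("pairwise FST satisfies its defining identities", {
  # fixed difference
  expect_equal(pairwise_fst(1, 0), 1)
  expect_equal(pairwise_fst(0, 1), 1)
  # identical frequencies
  for (p in c(0, 0.25, 0.5, 1)) expect_equal(pairwise_fst(p, p), 0)
  # hand evaluation: HT = 0.5, HS = 0.32 -> 0.36
  expect_equal(pairwise_fst(0.8, 0.2), 0.36)
  # symmetry and range over a random grid
  set.seed(4)
  p1 <- runif(200); p2 <- runif(200)
  f12 <- pairwise_fst(p1, p2)
  expect_equal(f12, pairwise_fst(p2, p1))
  expect_true(all(f12 >= 0 & f12 <= 1))
  # equals 1 only at fixed differences
  expect_true(all(f12[!(pmin(p1, p2) == 0 & pmax(p1, p2) == 1)] < 1))
  expect_error(pairwise_fst(1.2, 0.5), "\\[0, 1\\]")
})

test_that("site filter is monotone: loose admits a superset of stringent", {
  loose <- fst_settings("loose")
  stringent <- fst_settings("stringent")
  expect_lte(loose$min_depth, stringent$min_depth)
  # depth 15 passes loose (>=10) and fails stringent (>=30)
  tab <- freq_table_from(matrix(c(0.5, 0.5), ncol = 2), depth = 15L)
  el_loose <- site_filter(tab, loose)$eligible
  el_str <- site_filter(tab, stringent)$eligible
  expect_true(all(el_loose))
  expect_false(any(el_str))
  # zero depth in one pool: ineligible under any settings
  tab0 <- freq_table_from(matrix(c(0.5, 0.5), ncol = 2), depth = 40L)
  tab0$ref_depth[1, 2] <- 0L; tab0$alt_depth[1, 2] <- 0L
  tab0 <- pool_freq_table(tab0$snps, tab0$pools, tab0$ref_depth, tab0$alt_depth)
  expect_false(any(site_filter(tab0, fst_settings("loose", 1, 0))$eligible))
  # containment over random tables
  for (s in 1:5) {
    cfg <- toy_config(n_snps = 200L, n_ind = 2L, pool_coverage = 25)
    sim <- simulate_dataset(cfg, seed = s)
    el_l <- site_filter(sim$pool_table, loose)$eligible
    el_s <- site_filter(sim$pool_table, stringent)$eligible
    expect_true(all(el_l[el_s]))           # stringent => loose
    expect_gte(sum(el_l), sum(el_s))
  }
})

test_that("summed FST matches the brute-force double loop and its bound", {
  set.seed(7)
  freqs <- matrix(runif(100 * 5), ncol = 5)
  tab <- freq_table_from(freqs, depth = 100L)
  perm <- fst_settings("loose", min_depth = 1, min_minor_count = 0)
  for (focal in 1:5) {
    got <- summed_fst(tab, paste0("p", focal), perm)
    want <- summed_fst_bruteforce(tab$freq, focal)
    expect_equal(got$summed_fst[order(got$pos)], want, tolerance = 1e-12)
    expect_true(all(got$summed_fst <= ncol(freqs) - 1 + 1e-12))
  }
  expect_error(summed_fst(tab, "nope"), "unknown pool")
})

test_that("a SNP fixed in the focal pool and absent elsewhere saturates the bound", {
  # 22 pools: frequency 1 in pool 1, 0 in the other 21 -> sum = 21
  freqs <- matrix(0, nrow = 1, ncol = 22)
  freqs[1, 1] <- 1
  tab <- freq_table_from(freqs, depth = 100L)
  s <- summed_fst(tab, "p1", fst_settings("loose", 1, 0))
  expect_equal(s$summed_fst[1], 21)
  # 3 pools with freqs (1, 0, 0): two fixed-difference pairs -> 2
  tab3 <- freq_table_from(matrix(c(1, 0, 0), nrow = 1), depth = 100L)
  expect_equal(summed_fst(tab3, "p1", fst_settings("loose", 1, 0))$summed_fst[1], 2)
  # identical pools -> 0 everywhere
  tabeq <- freq_table_from(matrix(0.4, nrow = 5, ncol = 4), depth = 100L)
  expect_true(all(summed_fst(tabeq, "p2", fst_settings("loose", 1, 0))$summed_fst == 0))
})

test_that("panel selection fills quotas uniquely with skip-and-continue", {
  # 2 pools rank the same SNP first (both rankings are identical);
  # the first-processed pool takes it, the second continues down
  freqs <- cbind(c(0.9, 0.7, 0.6, 0.5, 0.5),
                 c(0.1, 0.3, 0.4, 0.5, 0.5))
  tab <- freq_table_from(freqs, depth = 100L)
  perm <- fst_settings("loose", 1, 0)
  pan <- select_fst_panel(tab, k_loose = 1L, k_stringent = 0L,
                          loose = perm, stringent = perm)
  expect_equal(nrow(pan), 2L)
  expect_equal(anyDuplicated(paste(pan$chrom, pan$pos)), 0L)
  expect_equal(pan$pos[pan$focal_unit == "p1"], 1L)  # top SNP
  expect_equal(pan$pos[pan$focal_unit == "p2"], 2L)  # next in line
  # 1 pool, quotas (1,1), 2 SNPs -> panel of 2
  tab1 <- freq_table_from(matrix(c(0.9, 0.2), ncol = 1), depth = 100L)
  pan1 <- select_fst_panel(tab1, k_loose = 1L, k_stringent = 1L,
                           loose = perm, stringent = perm)
  expect_equal(nrow(pan1), 2L)
  # shortfall: quota larger than eligible SNPs names the pool
  expect_error(select_fst_panel(tab, k_loose = 10L, k_stringent = 0L,
                                loose = perm, stringent = perm),
               "pool 'p1'")
})

test_that("FST selection is deterministic and records provenance", {
  cfg <- toy_config(n_snps = 300L, n_ind = 2L)
  sim <- simulate_dataset(cfg, seed = 12)
  a <- select_fst_panel(sim$pool_table, k_loose = 3L, k_stringent = 7L)
  b <- select_fst_panel(sim$pool_table, k_loose = 3L, k_stringent = 7L)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 4L * 10L)
  expect_setequal(unique(a$source), c("fst_loose", "fst_stringent"))
  expect_setequal(unique(a$focal_unit), cfg$pools)
  expect_equal(sum(a$source == "fst_stringent"), 4L * 7L)
})
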