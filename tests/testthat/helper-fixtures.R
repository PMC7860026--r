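# Shared fixtures: everything is built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# 2-lineage / 4-subspecies / 4-pool toy tree
toy_tree <- function() {
  data.frame(
    pool = paste0("p", 1:4),
    subspecies = paste0("s", 1:4),
    lineage = c("L1", "L1", "L2", "L2"),
    stringsAsFactors = FALSE
  )
}

toy_config <- function(n_snps = 400L, n_ind = 25L, ...) {
  hierarchy_config(toy_tree(), n_snps = n_snps, n_individuals_per_pool = n_ind,
                   quotas = list(global = 20L, L1 = 10L, L2 = 10L), ...)
}

# hand-built pool table: explicit frequencies at ample, constant depth
freq_table_from <- function(freqs, depth = 100L, pools = NULL) {
  freqs <- as.matrix(freqs)
  n <- nrow(freqs)
  if (is.null(pools)) pools <- paste0("p", seq_len(ncol(freqs)))
  snps <- data.frame(chrom = "chr1", pos = seq_len(n), ref = "A", alt = "C",
                     stringsAsFactors = FALSE)
  ref_depth <- round(freqs * depth)
  alt_depth <- depth - ref_depth
  pool_freq_table(snps, pools, ref_depth, alt_depth)
}

# brute-force oracle for summed pairwise FST: explicit double loop over
# pools, no filtering shortcuts (all sites assumed eligible at ample depth)
summed_fst_bruteforce <- function(freqs, focal) {
  freqs <- as.matrix(freqs)
  s <- numeric(nrow(freqs))
  for (i in seq_len(nrow(freqs))) {
    for (k in seq_len(ncol(freqs))) {
      if (k == focal) next
      p1 <- freqs[i, focal]; p2 <- freqs[i, k]
      pbar <- (p1 + p2) / 2
      ht <- 2 * pbar * (1 - pbar)
      hs <- p1 * (1 - p1) + p2 * (1 - p2)
      s[i] <- s[i] + if (ht > 0) (ht - hs) / ht else 0
    }
  }
  s
}

# small labeled genotype matrix with two well-separated classes
separable_genotypes <- function(n_per_class = 20L, n_snps = 60L, seed = 1L) {
  set.seed(seed)
  gA <- matrix(rbinom(n_per_class * n_snps, 2, 0.05), n_per_class)
  gB <- matrix(rbinom(n_per_class * n_snps, 2, 0.95), n_per_class)
  g <- rbind(gA, gB)
  rownames(g) <- paste0("ind", seq_len(nrow(g)))
  snps <- data.frame(chrom = "chr1", pos = seq_len(n_snps), ref = "A",
                     alt = "G", stringsAsFactors = FALSE)
  labels <- data.frame(
    sample_id = rownames(g),
    pool_id = rep(c("pA", "pB"), each = n_per_class),
    subspecies = rep(c("clsA", "clsB"), each = n_per_class),
    lineage = rep(c("LA", "LB"), each = n_per_class),
    stringsAsFactors = FALSE
  )
  genotype_matrix(g, snps, labels = labels)
}
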