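#' Balding-Nichols drift of allele frequencies
#'
#' Draws daughter-population frequencies from the Balding-Nichols model:
#' given a parent frequency p and divergence F, the child frequency is
#' Beta(p(1-F)/F, (1-p)(1-F)/F), independently per SNP. The child is
#' unbiased (E = p) with variance F p(1-p), so F is recoverable from
#' realized differentiation. Parent frequencies of exactly 0 or 1 are fixed
#' and stay fixed.
#'
#' @param parent_freqs numeric vector of parent frequencies in \[0, 1\].
#' @param F divergence parameter in (0, 1).
#' @param seed optional integer seed (uses the current RNG stream if NULL).
#' @return numeric vector of child frequencies, same length.
#' @export
drift_freqs <- function(parent_freqs, F, seed = NULL) {
  if (!is.numeric(F) || length(F) != 1L || F <= 0 || F >= 1) {
    stop("F must be a single number in (0, 1)")
  }
  if (any(parent_freqs < 0 | parent_freqs > 1)) {
    stop("parent frequencies must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  child <- parent_freqs
  seg <- parent_freqs > 0 & parent_freqs < 1
  p <- parent_freqs[seg]
  child[seg] <- stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  child
}

#' Simulate a hierarchically structured pool-seq + genotyping dataset
#'
#' Emulates the reference design end to end: ancestral frequencies are drawn
#' uniformly from the configured range, drifted down the
#' lineage -> subspecies -> pool tree by successive Balding-Nichols steps,
#' pooled sequencing adds Poisson depth and binomial read sampling, and
#' individual bees are drawn from their pool's true frequency
#' (alt-allele count ~ Binomial(2, 1 - p_ref)). Null alleles — probe
#' failures of the genotyping assay — are switched on per (subspecies, SNP)
#' at the configured rate and blank the affected genotypes; pooled
#' sequencing counts are unaffected, since the nulls are an array artifact.
#'
#' @param config a [hierarchy_config()].
#' @param seed integer master seed; all randomness derives from it and the
#'   output is bit-reproducible.
#' @param plant optional list(n=, gap=) to plant `n` lineage-diagnostic SNPs:
#'   for each planted SNP one lineage (cycled) is set to frequency
#'   0.5 + gap/2 and the others to 0.5 - gap/2 before subspecies-level
#'   drift, giving known ancestry-informative markers for recovery tests.
#' @return list with components `pool_table` ([pool_freq_table()]),
#'   `genotypes` ([genotype_matrix()] with labels), `labels` (data.frame),
#'   and `truth` (ancestral/lineage/subspecies/pool frequencies, planted
#'   flags, null-allele mask).
#' @export
simulate_dataset <- function(config, seed, plant = NULL) {
  stopifnot(inherits(config, "hierarchy_config"))
  set.seed(as.integer(seed))
  n <- config$n_snps
  tree <- config$tree
  lineages <- config$lineages
  subspecies <- config$subspecies
  pools <- config$pools

  rng <- config$ancestral_freq_range
  p0 <- stats::runif(n, rng[1], rng[2])

  lin_f <- sapply(lineages, function(l) drift_freqs(p0, config$f_lineage))
  planted <- rep(FALSE, n)
  if (!is.null(plant) && plant$n > 0) {
    if (plant$n > n) stop("cannot plant more AIMs than SNPs")
    idx <- sort(sample.int(n, plant$n))
    planted[idx] <- TRUE
    hi <- 0.5 + plant$gap / 2
    lo <- 0.5 - plant$gap / 2
    for (k in seq_along(idx)) {
      target <- 1L + (k - 1L) %% length(lineages)
      lin_f[idx[k], ] <- lo
      lin_f[idx[k], target] <- hi
    }
  }

  sub_f <- sapply(subspecies, function(s) {
    lin <- tree$lineage[match(s, tree$subspecies)]
    drift_freqs(lin_f[, lin], config$f_subspecies)
  })
  pool_f <- sapply(pools, function(pl) {
    s <- tree$subspecies[match(pl, tree$pool)]
    drift_freqs(sub_f[, s], config$f_pool)
  })

  # pooled sequencing: Poisson depth, binomial reads on the ref allele
  depth <- matrix(stats::rpois(n * length(pools), config$pool_coverage),
                  nrow = n)
  ref_depth <- matrix(stats::rbinom(n * length(pools), as.vector(depth),
                                    as.vector(pool_f)), nrow = n)
  alt_depth <- depth - ref_depth

  chrom <- paste0("chr", 1L + (seq_len(n) - 1L) %% 16L)
  pos <- 64L * (1L + (seq_len(n) - 1L) %/% 16L)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  snps <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
  pool_table <- pool_freq_table(snps, pools, ref_depth, alt_depth)

  # individual genotypes from the pools' TRUE frequencies
  n_ind <- config$n_individuals_per_pool
  g <- matrix(NA_integer_, nrow = n_ind * length(pools), ncol = n)
  sample_ids <- character(nrow(g))
  for (j in seq_along(pools)) {
    rows <- (j - 1L) * n_ind + seq_len(n_ind)
    q <- 1 - pool_f[, j]  # alt-allele frequency
    g[rows, ] <- matrix(stats::rbinom(n_ind * n, 2L, rep(q, each = n_ind)),
                        nrow = n_ind)
    sample_ids[rows] <- sprintf("%s_ind%03d", pools[j], seq_len(n_ind))
  }
  rownames(g) <- sample_ids
  labels <- data.frame(
    sample_id = sample_ids,
    pool_id = rep(pools, each = n_ind),
    subspecies = rep(tree$subspecies, each = n_ind),
    lineage = rep(tree$lineage, each = n_ind),
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(g, snps, labels = labels)

  null_mask <- matrix(
    stats::runif(length(subspecies) * n) <
      rep(config$null_allele_rate, times = n),
    nrow = length(subspecies), dimnames = list(subspecies, snp_id(snps))
  )
  gm <- apply_null_alleles(gm, null_mask)

  truth <- structure(
    list(ancestral = p0, lineage_freq = lin_f, subspecies_freq = sub_f,
         pool_freq = pool_f, planted = planted, null_mask = null_mask),
    class = "sim_truth"
  )
  list(pool_table = pool_table, genotypes = gm, labels = labels, truth = truth)
}

#' Simulate individual genotypes from pool allele frequencies
#'
#' Draws `n` individuals per pool with per-SNP genotypes from
#' Binomial(2, p) — Hardy-Weinberg sampling from the pool's frequency.
#' When a [pool_freq_table()] is supplied, p is the alternate-allele
#' frequency (so the genotype counts alt alleles, consistent with
#' [genotype_matrix()]); cells with zero depth, where the frequency is
#' undefined, are emitted as missing. A plain numeric matrix (SNPs x pools)
#' is interpreted as the frequency of the counted allele directly.
#'
#' @param pool_freqs a [pool_freq_table()] or numeric matrix/vector of
#'   frequencies in \[0, 1\] (a vector is one pool).
#' @param n individuals per pool.
#' @param seed integer seed.
#' @param pool_ids optional pool names for a bare matrix.
#' @return a [genotype_matrix()] labeled with the pool of origin
#'   (subspecies/lineage labels set to the pool id when unknown).
#' @export
sample_individuals_from_freqs <- function(pool_freqs, n, seed, pool_ids = NULL) {
  if (n < 1L) stop("n must be >= 1")
  set.seed(as.integer(seed))
  if (inherits(pool_freqs, "pool_freq_table")) {
    tab <- pool_freqs
    q <- 1 - tab$freq  # counted (alt) allele frequency, NA where undefined
    pools <- tab$pools
    snps <- tab$snps
  } else {
    q <- as.matrix(pool_freqs)
    if (any(q < 0 | q > 1, na.rm = TRUE)) stop("frequencies must lie in [0, 1]")
    pools <- if (!is.null(pool_ids)) pool_ids else
      if (!is.null(colnames(q))) colnames(q) else paste0("pool", seq_len(ncol(q)))
    snps <- data.frame(chrom = "sim", pos = seq_len(nrow(q)),
                       ref = "A", alt = "C", stringsAsFactors = FALSE)
  }
  n_snp <- nrow(q)
  g <- matrix(NA_integer_, nrow = n * length(pools), ncol = n_snp)
  for (j in seq_along(pools)) {
    rows <- (j - 1L) * n + seq_len(n)
    qj <- q[, j]
    ok <- !is.na(qj)
    block <- matrix(NA_integer_, n, n_snp)
    block[, ok] <- stats::rbinom(n * sum(ok), 2L, rep(qj[ok], each = n))
    g[rows, ] <- block
  }
  rownames(g) <- paste0(rep(pools, each = n), "_sim",
                        sprintf("%03d", rep(seq_len(n), length(pools))))
  labels <- data.frame(
    sample_id = rownames(g),
    pool_id = rep(pools, each = n),
    subspecies = rep(pools, each = n),
    lineage = rep(pools, each = n),
    stringsAsFactors = FALSE
  )
  genotype_matrix(g, snps, labels = labels)
}

#' Apply a subspecies-wide null-allele mask to genotypes
#'
#' Null alleles are modeled all-or-none per (subspecies, SNP): where the
#' mask is TRUE, every sample of that subspecies has its genotype at that
#' SNP set to missing — the signature of a subspecies-specific deletion or
#' variant under the genotyping probe. All other cells are untouched.
#'
#' @param gm a labeled [genotype_matrix()].
#' @param mask logical matrix, subspecies x SNPs; rownames must name the
#'   subspecies and columns must match the SNPs of `gm`.
#' @return the masked [genotype_matrix()].
#' @export
apply_null_alleles <- function(gm, mask) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$labels)) stop("genotype matrix must carry subspecies labels")
  if (ncol(mask) != ncol(gm$g)) {
    stop("null mask has ", ncol(mask), " SNP columns but genotypes have ", ncol(gm$g))
  }
  if (is.null(rownames(mask))) stop("null mask must have subspecies rownames")
  g <- gm$g
  for (s in rownames(mask)) {
    rows <- which(gm$labels$subspecies == s)
    if (length(rows) == 0L) next
    cols <- which(mask[s, ])
    if (length(cols) > 0L) g[rows, cols] <- NA_integer_
  }
  genotype_matrix(g, gm$snps, labels = gm$labels)
}

#' Recover the drift parameter F from a set of pool frequencies
#'
#' For pools drifted independently from a common parent, the
#' heterozygosity-form pairwise FST has expectation (F/2)/(1 - F/2), not F:
#' each of the two pools contributes its own variance F p(1-p) but the
#' pooled mean averages half of it away. The multilocus FST is taken as the
#' ratio of means sum(HT - HS) / sum(HT) (the standard multilocus form,
#' which avoids the per-SNP ratio's small-denominator noise), and inverting
#' the expectation gives the moment estimator F-hat = 2 FST / (1 + FST),
#' averaged over all pool pairs.
#'
#' @param freqs numeric matrix (SNPs x pools) of allele frequencies of
#'   sibling pools.
#' @return estimate of the per-pool divergence parameter F.
#' @export
estimate_drift_F <- function(freqs) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) < 2L) stop("need at least two pools")
  pairs <- utils::combn(ncol(freqs), 2L)
  fst <- mean(apply(pairs, 2L, function(jk) {
    p1 <- freqs[, jk[1L]]
    p2 <- freqs[, jk[2L]]
    ok <- !is.na(p1) & !is.na(p2)
    pbar <- (p1[ok] + p2[ok]) / 2
    ht <- 2 * pbar * (1 - pbar)
    hs <- p1[ok] * (1 - p1[ok]) + p2[ok] * (1 - p2[ok])
    sum(ht - hs) / sum(ht)
  }))
  2 * fst / (1 + fst)
}
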