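#' Site-filter settings for pooled FST
#'
#' Two filtering regimes mirror the usual pooled-data trade-off: a loose
#' setting admits more sites with less certainty (raising the chance of
#' catching rare population-unique variants), a stringent setting keeps only
#' well-supported sites. A pool pair is eligible at a site iff both pools
#' reach `min_depth` and the pair's minor-allele read count reaches
#' `min_minor_count`.
#'
#' @param mode `"loose"` or `"stringent"`; fills in the defaults
#'   (loose: depth >= 10, minor count >= 2; stringent: depth >= 30,
#'   minor count >= 4).
#' @param min_depth minimum read depth per pool (>= 1).
#' @param min_minor_count minimum minor-allele count across the pair (>= 0).
#' @return an object of class `fst_settings`.
#' @export
fst_settings <- function(mode = c("loose", "stringent"),
                         min_depth = NULL, min_minor_count = NULL) {
  mode <- match.arg(mode)
  defaults <- list(loose = c(10L, 2L), stringent = c(30L, 4L))[[mode]]
  if (is.null(min_depth)) min_depth <- defaults[1L]
  if (is.null(min_minor_count)) min_minor_count <- defaults[2L]
  if (min_depth < 1L) stop("min_depth must be >= 1")
  if (min_minor_count < 0L) stop("min_minor_count must be >= 0")
  structure(list(mode = mode, min_depth = as.integer(min_depth),
                 min_minor_count = as.integer(min_minor_count)),
            class = "fst_settings")
}

#' Pairwise FST between two allele frequencies
#'
#' Heterozygosity form: with pbar = (p1+p2)/2, HT = 2 pbar (1-pbar) and
#' HS = (2 p1 (1-p1) + 2 p2 (1-p2)) / 2, FST = (HT - HS) / HT, defined as 0
#' where HT = 0 (both pools fixed for the same allele). Symmetric, in
#' \[0, 1\], and equal to 1 exactly at a fixed difference ({p1,p2} = {0,1}).
#' Vectorized over SNPs; NA in, NA out.
#'
#' @param p1,p2 numeric vectors of allele frequencies in \[0, 1\].
#' @return numeric vector of FST values.
#' @export
pairwise_fst <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1, na.rm = TRUE) || any(p2 < 0 | p2 > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- p1 * (1 - p1) + p2 * (1 - p2)
  fst <- ifelse(ht > 0, (ht - hs) / ht, 0)
  # clamp tiny negative round-off
  pmin(pmax(fst, 0), 1)
}

#' Per-pair site eligibility under a filter setting
#'
#' @param table a [pool_freq_table()].
#' @param settings an [fst_settings()].
#' @return list with `pairs` (2 x n_pairs index matrix over pools) and
#'   `eligible` (n_snps x n_pairs logical): a pair is eligible at a SNP iff
#'   both pools' depth >= min_depth and the pair's pooled minor-allele count
#'   >= min_minor_count. Ineligible pairs contribute 0 to summed FST.
#' @export
site_filter <- function(table, settings) {
  stopifnot(inherits(table, "pool_freq_table"), inherits(settings, "fst_settings"))
  depth <- table$ref_depth + table$alt_depth
  pairs <- utils::combn(length(table$pools), 2L)
  eligible <- apply(pairs, 2L, function(jk) {
    j <- jk[1L]; k <- jk[2L]
    ref2 <- table$ref_depth[, j] + table$ref_depth[, k]
    alt2 <- table$alt_depth[, j] + table$alt_depth[, k]
    depth[, j] >= settings$min_depth &
      depth[, k] >= settings$min_depth &
      pmin(ref2, alt2) >= settings$min_minor_count
  })
  eligible <- matrix(eligible, nrow = nrow(table$snps))
  list(pairs = pairs, eligible = eligible)
}

#' Summed pairwise FST of one pool against all others
#'
#' For a focal pool j, S_i = sum over all other pools k of FST(p_ij, p_ik)
#' at SNP i, counting only (j,k) pairs that pass the site filter. A SNP
#' fixed in the focal pool and absent everywhere else saturates the bound
#' S = n_pools - 1 (each of the other pools contributes a fixed-difference
#' FST of 1). SNPs are ranked by descending S with ties broken by
#' (chrom, pos).
#'
#' @param table a [pool_freq_table()].
#' @param pool_id focal pool id.
#' @param settings an [fst_settings()].
#' @return data.frame, one row per SNP in rank order: `chrom`, `pos`,
#'   `ref`, `alt`, `summed_fst`, `n_pairs` (eligible pairs), `eligible`
#'   (>= 1 eligible pair), `rank`.
#' @export
summed_fst <- function(table, pool_id, settings = fst_settings("loose")) {
  stopifnot(inherits(table, "pool_freq_table"))
  j <- match(pool_id, table$pools)
  if (is.na(j)) stop("unknown pool id: ", pool_id)
  depth <- table$ref_depth + table$alt_depth
  s <- numeric(nrow(table$snps))
  n_pairs <- integer(nrow(table$snps))
  for (k in seq_along(table$pools)) {
    if (k == j) next
    # pair eligibility under the site filter (same rule as site_filter())
    ref2 <- table$ref_depth[, j] + table$ref_depth[, k]
    alt2 <- table$alt_depth[, j] + table$alt_depth[, k]
    ok <- depth[, j] >= settings$min_depth &
      depth[, k] >= settings$min_depth &
      pmin(ref2, alt2) >= settings$min_minor_count &
      !is.na(table$freq[, j]) & !is.na(table$freq[, k])
    fst <- pairwise_fst(table$freq[, j], table$freq[, k])
    s <- s + ifelse(ok, fst, 0)
    n_pairs <- n_pairs + ok
  }
  # a single-pool table has no pairs; every SNP is then vacuously eligible
  out <- data.frame(table$snps, summed_fst = s, n_pairs = n_pairs,
                    eligible = n_pairs >= 1L | length(table$pools) == 1L,
                    stringsAsFactors = FALSE)
  ord <- order(-out$summed_fst, out$chrom, out$pos)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the FST branch of the marker panel
#'
#' Every pool contributes its top-ranked SNPs by summed pairwise FST:
#' `k_stringent` from the stringent ranking, then `k_loose` from the loose
#' ranking. A SNP already selected — by an earlier pool, the other setting,
#' or the `exclude` list (e.g. the PCA branch) — is skipped and the ranking
#' is walked further down, so each pool contributes exactly
#' `k_loose + k_stringent` unique SNPs and the panel size is exactly
#' `n_pools * (k_loose + k_stringent)`. Pools are processed in table order;
#' at exact score ties the (chrom, pos) tie-break makes the result
#' deterministic.
#'
#' @param table a [pool_freq_table()].
#' @param k_loose,k_stringent per-pool quotas (defaults 20 and 80).
#' @param loose,stringent the two [fst_settings()].
#' @param exclude character vector of `chrom:pos` SNP ids to skip.
#' @return a [panel_manifest()] with sources `fst_stringent` / `fst_loose`
#'   and the focal pool as `focal_unit`.
#' @export
select_fst_panel <- function(table, k_loose = 20L, k_stringent = 80L,
                             loose = fst_settings("loose"),
                             stringent = fst_settings("stringent"),
                             exclude = character(0)) {
  stopifnot(inherits(table, "pool_freq_table"))
  taken <- new.env(parent = emptyenv())
  for (id in exclude) assign(id, TRUE, envir = taken)
  rows <- vector("list", length(table$pools) * 2L)
  ri <- 0L
  take <- function(ranking, quota, source, pool) {
    ranking <- ranking[ranking$eligible, , drop = FALSE]
    ids <- paste(ranking$chrom, ranking$pos, sep = ":")
    picked <- integer(0)
    for (i in seq_along(ids)) {
      if (length(picked) == quota) break
      if (!is.null(taken[[ids[i]]])) next
      assign(ids[i], TRUE, envir = taken)
      picked <- c(picked, i)
    }
    if (length(picked) < quota) {
      stop("pool '", pool, "': only ", length(picked),
           " eligible unselected SNPs for the ", source,
           " quota of ", quota)
    }
    data.frame(ranking[picked, c("chrom", "pos", "ref", "alt")],
               source = source, focal_unit = pool,
               score = ranking$summed_fst[picked],
               stringsAsFactors = FALSE)
  }
  for (pool in table$pools) {
    if (k_stringent > 0L) {
      ri <- ri + 1L
      rows[[ri]] <- take(summed_fst(table, pool, stringent), k_stringent,
                         "fst_stringent", pool)
    }
    if (k_loose > 0L) {
      ri <- ri + 1L
      rows[[ri]] <- take(summed_fst(table, pool, loose), k_loose,
                         "fst_loose", pool)
    }
  }
  panel_manifest(do.call(rbind, rows[seq_len(ri)]))
}
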