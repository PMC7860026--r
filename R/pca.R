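#' Minor-allele-frequency matrix for a pool subset
#'
#' Builds the pools x SNPs matrix the PCA branch operates on. Within the
#' chosen subset of pools, the minor allele of each SNP is the allele with
#' mean frequency <= 0.5 across the subset (ties go to the alt allele), and
#' each cell holds that allele's frequency. Cells where the frequency is
#' undefined (zero depth) are imputed with the SNP's subset mean; SNPs
#' undefined in every subset pool are dropped with a warning.
#'
#' @param table a [pool_freq_table()].
#' @param pool_subset character vector of pool ids (default: all pools).
#' @return numeric matrix (pools x SNPs) with values in \[0, 1\]; column
#'   names are the `chrom:pos` SNP ids of the retained SNPs.
#' @export
build_maf_matrix <- function(table, pool_subset = NULL) {
  stopifnot(inherits(table, "pool_freq_table"))
  if (is.null(pool_subset)) pool_subset <- table$pools
  j <- match(pool_subset, table$pools)
  if (anyNA(j)) stop("unknown pool id: ", pool_subset[is.na(j)][1L])
  if (length(j) == 0L) stop("pool subset is empty")
  p_ref <- table$freq[, j, drop = FALSE]  # SNPs x subset pools
  all_missing <- rowSums(!is.na(p_ref)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " SNP(s) undefined in every subset pool dropped")
    p_ref <- p_ref[!all_missing, , drop = FALSE]
  }
  mean_ref <- rowMeans(p_ref, na.rm = TRUE)
  # minor allele: mean freq <= 0.5; ties (mean exactly 0.5) go to alt
  minor_is_ref <- mean_ref < 0.5
  maf <- p_ref
  maf[!minor_is_ref, ] <- 1 - p_ref[!minor_is_ref, , drop = FALSE]
  # mean imputation of undefined cells, on the minor-allele scale
  snp_mean <- rowMeans(maf, na.rm = TRUE)
  idx <- which(is.na(maf), arr.ind = TRUE)
  if (nrow(idx) > 0) maf[idx] <- snp_mean[idx[, 1L]]
  out <- t(maf)
  rownames(out) <- pool_subset
  out
}

#' PCA of a frequency matrix
#'
#' Centered, unit-variance PCA of the pools x SNPs matrix (correlation
#' convention, so the eigenvalues sum to the number of retained columns).
#' Zero-variance SNP columns carry no information at this level and are
#' dropped before scaling. Variable (SNP) coordinates follow the
#' correlation convention: coord(snp, k) = loading(snp, k) * sqrt(lambda_k).
#'
#' @param x numeric matrix, units (pools) x variables (SNPs); >= 2 rows.
#' @param level label recorded on the result (e.g. `"global"` or a lineage).
#' @return object of class `pca_result`: `eigenvalues` (descending),
#'   `coord` (SNPs x PCs), `scores` (pools x PCs), `retained` (SNP ids
#'   kept), `dropped` (zero-variance SNP ids), `level`.
#' @export
run_pca <- function(x, level = "global") {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 pools")
  if (ncol(x) < 2L) stop("PCA needs at least 2 SNPs")
  v <- apply(x, 2L, stats::var)
  keep <- v > 0
  dropped <- colnames(x)[!keep]
  x <- x[, keep, drop = FALSE]
  if (ncol(x) < 1L) stop("no variable SNP columns at this level")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  lambda <- pc$sdev^2
  coord <- sweep(pc$rotation, 2L, pc$sdev, `*`)
  structure(
    list(eigenvalues = lambda, coord = coord, scores = pc$x,
         rotation = pc$rotation, retained = colnames(x), dropped = dropped,
         level = level),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result (level ", x$level, "): ", length(x$retained), " SNPs, ",
      length(x$eigenvalues), " PCs; top eigenvalues: ",
      paste(round(utils::head(x$eigenvalues, 3), 2), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Significant principal components
#'
#' Kaiser-style above-average rule: PCs whose eigenvalue exceeds the mean
#' eigenvalue are retained. At least one PC is always returned (if no
#' eigenvalue strictly exceeds the mean — all equal — PC1 is used).
#'
#' @param result a [run_pca()] result.
#' @return integer vector of PC indices.
#' @export
significant_pcs <- function(result) {
  lambda <- result$eigenvalues
  sig <- which(lambda > mean(lambda))
  if (length(sig) == 0L) sig <- 1L
  sig
}

#' Per-SNP contribution scores over a set of PCs
#'
#' The contribution of a SNP to PC k is ctr(snp, k) =
#' 100 * coord(snp, k)^2 / lambda_k, which sums to 100 over SNPs for each
#' PC. Scores are aggregated over the chosen PCs with eigenvalue-share
#' weights, so dominant axes dominate selection:
#' score = sum_k (lambda_k / sum lambda) * ctr(snp, k). PCs with a zero
#' eigenvalue are skipped. SNPs dropped at this level (zero variance) score 0.
#'
#' @param result a [run_pca()] result.
#' @param pcs integer vector of PC indices (default [significant_pcs()]).
#' @return named numeric vector of scores over all SNPs seen by the level
#'   (retained and dropped).
#' @export
snp_contribution <- function(result, pcs = significant_pcs(result)) {
  if (any(pcs < 1L | pcs > length(result$eigenvalues))) {
    stop("PC index out of range")
  }
  lambda <- result$eigenvalues[pcs]
  live <- lambda > .Machine$double.eps
  pcs <- pcs[live]
  lambda <- lambda[live]
  if (length(pcs) == 0L) stop("all requested PCs have zero eigenvalue")
  ctr <- sweep(result$coord[, pcs, drop = FALSE]^2, 2L,
               result$eigenvalues[pcs], `/`) * 100
  w <- lambda / sum(lambda)
  score <- drop(ctr %*% w)
  out <- stats::setNames(numeric(length(result$retained) + length(result$dropped)),
                         c(result$retained, result$dropped))
  out[result$retained] <- score
  out
}

#' Hierarchical PCA selection of ancestry-informative SNPs
#'
#' Two-stage selection mirroring the population hierarchy: a global PCA
#' over all pools picks SNPs separating the evolutionary lineages, then a
#' PCA restricted to each lineage's pools picks SNPs separating the
#' subspecies within it. At each level the top-quota SNPs by aggregate
#' contribution to the significant PCs are taken, skipping SNPs already
#' selected at an earlier level (global first, then lineages in hierarchy
#' order). Ties in score are broken by (chrom, pos).
#'
#' @param table a [pool_freq_table()].
#' @param hierarchy a [hierarchy_config()] naming each pool's lineage.
#' @param quotas named list of per-level quotas (`global` plus one entry
#'   per lineage); defaults to `hierarchy$quotas`.
#' @param exclude character vector of `chrom:pos` ids to skip.
#' @return a [panel_manifest()] with sources `pca_global` / `pca_<lineage>`.
#' @export
hierarchical_pca_select <- function(table, hierarchy, quotas = NULL,
                                    exclude = character(0)) {
  stopifnot(inherits(table, "pool_freq_table"), inherits(hierarchy, "hierarchy_config"))
  if (is.null(quotas)) quotas <- hierarchy$quotas
  taken <- new.env(parent = emptyenv())
  for (id in exclude) assign(id, TRUE, envir = taken)
  levels_ <- c(list(c(level = "global")),
               lapply(hierarchy$lineages, function(l) c(level = l)))
  rows <- list()
  for (lv in levels_) {
    level <- lv[["level"]]
    quota <- if (level == "global") quotas$global else quotas[[level]]
    if (is.null(quota) || quota == 0L) next
    pool_subset <- if (level == "global") hierarchy$pools else
      hierarchy$tree$pool[hierarchy$tree$lineage == level]
    if (length(pool_subset) < 2L) {
      stop("level '", level, "' has fewer than 2 pools; set its quota to 0")
    }
    maf <- build_maf_matrix(table, pool_subset)
    pca <- run_pca(maf, level = level)
    score <- snp_contribution(pca)
    ids <- names(score)
    info <- table$snps[match(ids, snp_id(table$snps)), ]
    ord <- order(-score, info$chrom, info$pos)
    picked <- integer(0)
    for (i in ord) {
      if (length(picked) == quota) break
      if (!is.null(taken[[ids[i]]])) next
      assign(ids[i], TRUE, envir = taken)
      picked <- c(picked, i)
    }
    if (length(picked) < quota) {
      stop("level '", level, "': only ", length(picked),
           " unselected SNPs available for quota ", quota)
    }
    src <- if (level == "global") "pca_global" else paste0("pca_", level)
    rows[[length(rows) + 1L]] <- data.frame(
      info[picked, c("chrom", "pos", "ref", "alt")],
      source = src, focal_unit = level, score = unname(score[picked]),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(panel_manifest(data.frame()))
  panel_manifest(do.call(rbind, rows), hierarchy = hierarchy)
}

#' Build the full two-branch marker panel
#'
#' Runs the hierarchical PCA selection first, then the per-pool summed-FST
#' selection with the PCA picks excluded, and concatenates the two
#' manifests. With the reference quotas (global 300 + within-lineage
#' 1100/200/600, and 20 loose + 80 stringent per pool over 22 pools) the
#' merged panel has exactly 4400 unique SNPs.
#'
#' @param table a [pool_freq_table()].
#' @param hierarchy a [hierarchy_config()].
#' @param quotas PCA quotas (default `hierarchy$quotas`).
#' @param k_loose,k_stringent per-pool FST quotas.
#' @param loose,stringent [fst_settings()] for the two regimes.
#' @param fst_first process the FST branch before the PCA branch (default
#'   FALSE: PCA first).
#' @return a [panel_manifest()] combining both branches.
#' @export
build_panel <- function(table, hierarchy, quotas = NULL,
                        k_loose = 20L, k_stringent = 80L,
                        loose = fst_settings("loose"),
                        stringent = fst_settings("stringent"),
                        fst_first = FALSE) {
  if (fst_first) {
    fst <- select_fst_panel(table, k_loose, k_stringent, loose, stringent)
    pca <- hierarchical_pca_select(table, hierarchy, quotas,
                                   exclude = snp_id(fst))
  } else {
    pca <- hierarchical_pca_select(table, hierarchy, quotas)
    fst <- select_fst_panel(table, k_loose, k_stringent, loose, stringent,
                            exclude = snp_id(pca))
  }
  panel_manifest(rbind(as.data.frame(pca), as.data.frame(fst)),
                 hierarchy = hierarchy)
}
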