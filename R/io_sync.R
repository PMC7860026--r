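#' Pooled allele-frequency table
#'
#' Container for per-SNP, per-pool biallelic read counts from pooled
#' sequencing and the derived reference-allele frequencies. Frequencies are
#' stored as reference-allele frequencies p = ref/(ref+alt); which allele is
#' "minor" flips between pools and is resolved where it matters (the PCA
#' minor-allele-frequency matrix, [build_maf_matrix()]).
#'
#' @param snps data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; ref != alt, both in A/C/G/T.
#' @param pools character vector of unique pool ids.
#' @param ref_depth,alt_depth integer matrices (snps x pools) of read counts
#'   supporting the reference and alternate allele.
#' @return an object of class `pool_freq_table` with a `freq` matrix that is
#'   `NA` exactly where total depth is zero.
#' @export
pool_freq_table <- function(snps, pools, ref_depth, alt_depth) {
  snps <- validate_snp_keys(snps)
  pools <- as.character(pools)
  if (anyDuplicated(pools) > 0) stop("pool ids must be unique")
  ref_depth <- as.matrix(ref_depth)
  alt_depth <- as.matrix(alt_depth)
  if (!all(dim(ref_depth) == c(nrow(snps), length(pools))) ||
      !all(dim(alt_depth) == c(nrow(snps), length(pools)))) {
    stop("depth matrices must be n_snps x n_pools")
  }
  if (any(ref_depth < 0) || any(alt_depth < 0)) stop("depths must be >= 0")
  storage.mode(ref_depth) <- "integer"
  storage.mode(alt_depth) <- "integer"
  dimnames(ref_depth) <- dimnames(alt_depth) <- list(snp_id(snps), pools)
  total <- ref_depth + alt_depth
  freq <- ifelse(total > 0, ref_depth / total, NA_real_)
  dimnames(freq) <- dimnames(ref_depth)
  structure(
    list(snps = snps, pools = pools,
         ref_depth = ref_depth, alt_depth = alt_depth, freq = freq),
    class = "pool_freq_table"
  )
}

#' @export
print.pool_freq_table <- function(x, ...) {
  cat("pool_freq_table:", nrow(x$snps), "SNPs x", length(x$pools), "pools\n")
  cat("  mean depth:", round(mean(x$ref_depth + x$alt_depth), 1),
      "| undefined cells:", sum(is.na(x$freq)), "\n")
  invisible(x)
}

# internal: canonical "chrom:pos" SNP identifier
snp_id <- function(snps) paste(snps$chrom, snps$pos, sep = ":")

# internal: validate a SNP key data.frame (chrom, pos, ref, alt)
validate_snp_keys <- function(snps) {
  stopifnot(is.data.frame(snps), all(c("chrom", "pos", "ref", "alt") %in% names(snps)))
  snps <- data.frame(
    chrom = as.character(snps$chrom), pos = as.integer(snps$pos),
    ref = as.character(snps$ref), alt = as.character(snps$alt),
    stringsAsFactors = FALSE
  )
  bases <- c("A", "C", "G", "T")
  if (any(snps$pos < 1L)) stop("SNP positions must be >= 1 (1-based)")
  if (!all(snps$ref %in% bases) || !all(snps$alt %in% bases)) {
    stop("ref/alt alleles must be one of A, C, G, T")
  }
  if (any(snps$ref == snps$alt)) stop("ref and alt allele must differ")
  rownames(snps) <- NULL
  snps
}

# base order used in the sync format columns
SYNC_BASES <- c("A", "T", "C", "G")

#' Read a PoPoolation2 sync file into a pool frequency table
#'
#' The sync format carries one line per site: chromosome, 1-based position,
#' reference base, then one `A:T:C:G:N:del` count column per pool. Sites are
#' reduced to biallelic form: the alternate allele is the non-reference base
#' with the highest summed count across pools (ties broken in base order
#' A < C < G < T). Sites where a third allele is observed above a small
#' read-noise floor are flagged and, by default, dropped — pooled callers do
#' not report how such sites should enter pairwise FST, and a biallelic
#' genotyping panel cannot use them.
#'
#' @param path sync file path (whitespace-delimited, optional `#` comments).
#' @param pools optional pool ids for the count columns (default `pool1..n`).
#' @param drop_triallelic drop flagged multi-allelic sites (default TRUE;
#'   if FALSE they are kept, reduced to their top two alleles).
#' @param noise_floor a third allele with more than this many reads (summed
#'   over pools) marks the site as multi-allelic.
#' @return a [pool_freq_table()]; the flagged site count is reported in a
#'   message when nonzero.
#' @export
read_sync <- function(path, pools = NULL, drop_triallelic = TRUE, noise_floor = 1L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("sync file is empty: ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  n_col <- lengths(fields)
  if (any(n_col != n_col[1L])) {
    bad <- which(n_col != n_col[1L])[1L]
    stop("sync parse error at line ", bad, ": expected ", n_col[1L],
         " fields, found ", n_col[bad])
  }
  n_pools <- n_col[1L] - 3L
  if (n_pools < 1L) stop("sync format error: no pool columns found")
  if (is.null(pools)) pools <- paste0("pool", seq_len(n_pools))
  if (length(pools) != n_pools) {
    stop("sync format error: ", n_pools, " pool columns but ",
         length(pools), " pool ids supplied")
  }
  m <- do.call(rbind, fields)
  chrom <- m[, 1L]
  pos <- suppressWarnings(as.integer(m[, 2L]))
  ref <- toupper(m[, 3L])
  if (anyNA(pos)) {
    stop("sync parse error at line ", which(is.na(pos))[1L], ": bad position")
  }
  if (!all(ref %in% SYNC_BASES)) {
    stop("sync parse error at line ", which(!ref %in% SYNC_BASES)[1L],
         ": reference base not in A/T/C/G")
  }
  # counts[site, base, pool], bases in sync order A:T:C:G (N/del ignored)
  n_sites <- nrow(m)
  counts <- array(0L, dim = c(n_sites, 4L, n_pools))
  for (j in seq_len(n_pools)) {
    parts <- strsplit(m[, 3L + j], ":", fixed = TRUE)
    if (any(lengths(parts) != 6L)) {
      stop("sync parse error at line ", which(lengths(parts) != 6L)[1L],
           ": pool column must have 6 ':'-separated counts")
    }
    cnt <- suppressWarnings(matrix(as.integer(unlist(parts)), ncol = 6L, byrow = TRUE))
    if (anyNA(cnt)) {
      stop("sync parse error at line ", which(rowSums(is.na(cnt)) > 0)[1L],
           ": non-integer count")
    }
    counts[, , j] <- cnt[, 1:4]
  }
  totals <- apply(counts, c(1, 2), sum)  # site x base, summed over pools
  ref_idx <- match(ref, SYNC_BASES)
  nonref <- totals
  nonref[cbind(seq_len(n_sites), ref_idx)] <- -1L
  # alt = non-ref base with max summed count; ties broken A < C < G < T
  tie_order <- order(match(SYNC_BASES, c("A", "C", "G", "T")))
  alt_idx <- apply(nonref[, tie_order, drop = FALSE], 1L, which.max)
  alt_idx <- tie_order[alt_idx]
  # sites with no non-ref reads at all: pick first base != ref in A<C<G<T order
  none <- nonref[cbind(seq_len(n_sites), alt_idx)] <= 0L
  if (any(none)) {
    for (i in which(none)) {
      cand <- setdiff(c("A", "C", "G", "T"), ref[i])[1L]
      alt_idx[i] <- match(cand, SYNC_BASES)
    }
  }
  third <- totals
  third[cbind(seq_len(n_sites), ref_idx)] <- 0L
  third[cbind(seq_len(n_sites), alt_idx)] <- 0L
  flagged <- apply(third, 1L, max) > noise_floor
  if (any(flagged)) {
    message(sum(flagged), " site(s) with >2 alleles above the noise floor",
            if (drop_triallelic) " dropped" else " kept (reduced to top two alleles)")
  }
  keep <- if (drop_triallelic) !flagged else rep(TRUE, n_sites)
  if (!any(keep)) stop("no biallelic sites left after filtering")
  ref_depth <- sapply(seq_len(n_pools), function(j) counts[cbind(seq_len(n_sites), ref_idx, j)])
  alt_depth <- sapply(seq_len(n_pools), function(j) counts[cbind(seq_len(n_sites), alt_idx, j)])
  ref_depth <- matrix(ref_depth, nrow = n_sites)
  alt_depth <- matrix(alt_depth, nrow = n_sites)
  snps <- data.frame(chrom = chrom, pos = pos, ref = ref,
                     alt = SYNC_BASES[alt_idx], stringsAsFactors = FALSE)
  pool_freq_table(snps[keep, , drop = FALSE], pools,
                  ref_depth[keep, , drop = FALSE], alt_depth[keep, , drop = FALSE])
}

#' Write a pool frequency table as a sync file
#'
#' Inverse of [read_sync()]: ref/alt depths are written into their base's
#' slot of the `A:T:C:G:N:del` column (other slots zero), so depths
#' round-trip exactly.
#'
#' @param table a [pool_freq_table()].
#' @param path output path.
#' @export
write_sync <- function(table, path) {
  stopifnot(inherits(table, "pool_freq_table"))
  n <- nrow(table$snps)
  ref_slot <- match(table$snps$ref, SYNC_BASES)
  alt_slot <- match(table$snps$alt, SYNC_BASES)
  cols <- vapply(seq_along(table$pools), function(j) {
    cnt <- matrix(0L, nrow = n, ncol = 6L)
    cnt[cbind(seq_len(n), ref_slot)] <- table$ref_depth[, j]
    cnt[cbind(seq_len(n), alt_slot)] <- table$alt_depth[, j]
    apply(cnt, 1L, paste, collapse = ":")
  }, character(n))
  cols <- matrix(cols, nrow = n)
  out <- cbind(table$snps$chrom, table$snps$pos, table$snps$ref, cols)
  writeLines(apply(out, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Write / read a pool frequency table as TSV
#'
#' Long-format TSV (`chrom pos ref alt pool ref_depth alt_depth`) with a
#' `#`-prefixed header; a plain-text alternative to the sync format that
#' preserves the chosen alt allele explicitly.
#'
#' @param table a [pool_freq_table()].
#' @param path file path.
#' @return `read_freq_tsv` returns a [pool_freq_table()].
#' @export
write_freq_tsv <- function(table, path) {
  stopifnot(inherits(table, "pool_freq_table"))
  long <- data.frame(
    chrom = rep(table$snps$chrom, times = length(table$pools)),
    pos = rep(table$snps$pos, times = length(table$pools)),
    ref = rep(table$snps$ref, times = length(table$pools)),
    alt = rep(table$snps$alt, times = length(table$pools)),
    pool = rep(table$pools, each = nrow(table$snps)),
    ref_depth = as.vector(table$ref_depth),
    alt_depth = as.vector(table$alt_depth)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(long), collapse = "\t")), con)
  utils::write.table(long, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_freq_tsv
#' @export
read_freq_tsv <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  long <- utils::read.table(path, sep = "\t", col.names = cols,
                            stringsAsFactors = FALSE)
  key <- paste(long$chrom, long$pos, sep = ":")
  snps <- unique(long[, c("chrom", "pos", "ref", "alt")])
  pools <- unique(long$pool)
  ids <- paste(snps$chrom, snps$pos, sep = ":")
  ref_depth <- matrix(0L, nrow(snps), length(pools))
  alt_depth <- matrix(0L, nrow(snps), length(pools))
  i <- match(key, ids)
  j <- match(long$pool, pools)
  ref_depth[cbind(i, j)] <- long$ref_depth
  alt_depth[cbind(i, j)] <- long$alt_depth
  pool_freq_table(snps, pools, ref_depth, alt_depth)
}
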