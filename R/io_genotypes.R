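#' Individual genotype matrix
#'
#' Samples x SNPs matrix of alternate-allele counts: 0 (hom-ref), 1 (het),
#' 2 (hom-alt) or `NA` (missing / no signal). Optional per-sample labels
#' carry the pool, subspecies and lineage of origin.
#'
#' @param g integer matrix (samples x snps), values in {0,1,2,NA}; rownames
#'   are sample ids.
#' @param snps SNP key data.frame (`chrom`, `pos`, `ref`, `alt`).
#' @param labels optional data.frame with columns `sample_id`, `pool_id`,
#'   `subspecies`, `lineage`, one row per sample of `g`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(g, snps, labels = NULL) {
  snps <- validate_snp_keys(snps)
  g <- as.matrix(g)
  storage.mode(g) <- "integer"
  if (ncol(g) != nrow(snps)) stop("g must have one column per SNP")
  if (!all(g %in% c(0L, 1L, 2L) | is.na(g))) {
    stop("genotypes must be 0, 1, 2 or NA")
  }
  if (is.null(rownames(g))) rownames(g) <- paste0("sample", seq_len(nrow(g)))
  colnames(g) <- snp_id(snps)
  if (!is.null(labels)) {
    labels <- as.data.frame(labels, stringsAsFactors = FALSE)
    need <- c("sample_id", "pool_id", "subspecies", "lineage")
    stopifnot(all(need %in% names(labels)))
    if (!setequal(labels$sample_id, rownames(g)) || anyDuplicated(labels$sample_id) > 0) {
      stop("labels must cover each sample id exactly once")
    }
    labels <- labels[match(rownames(g), labels$sample_id), need]
    rownames(labels) <- NULL
  }
  structure(list(g = g, snps = snps, labels = labels), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$g), "samples x", ncol(x$g), "SNPs;",
      round(100 * mean(is.na(x$g)), 1), "% missing\n")
  if (!is.null(x$labels)) {
    cat("  classes:", paste(unique(x$labels$subspecies), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read genotypes from a VCF file
#'
#' Reads the GT field of a VCF (4.x) into a [genotype_matrix()]. Only
#' biallelic records are usable on a biallelic SNP panel; multiallelic
#' records are skipped with a warning. `0/0 -> 0`, `0/1` or `1/0 -> 1`,
#' `1/1 -> 2`, `./. -> NA`; phased separators are accepted.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param labels optional label data.frame passed to [genotype_matrix()].
#' @return a [genotype_matrix()] with samples in VCF column order.
#' @export
read_vcf_genotypes <- function(path, labels = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!"GT" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID &&
      !grepl("GT", v@gt[1, 1])) {
    stop("VCF format error: no GT field")
  }
  bi <- vcfR::is.biallelic(v)
  if (any(!bi)) {
    warning(sum(!bi), " multiallelic record(s) skipped")
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% "0/0"] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% "1/1"] <- 2L
  fix <- vcfR::getFIX(v)
  if (!is.matrix(fix)) {  # single-record VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  snps <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  genotype_matrix(t(code), snps, labels = labels)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits an uncompressed VCF 4.2 with GT-only FORMAT, suitable for
#' round-tripping through [read_vcf_genotypes()] and for exchange with
#' standard tooling.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$g + 1L], nrow = nrow(gm$g))
  gt_str[is.na(gm$g)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=aimpanel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm$g)), collapse = "\t")
  ), con)
  body <- cbind(gm$snps$chrom, gm$snps$pos, snp_id(gm$snps), gm$snps$ref,
                gm$snps$alt, ".", "PASS", ".", "GT", t(gt_str))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write / read a genotype matrix as TSV
#'
#' Wide TSV with a `#`-prefixed header row: `sample_id` then one column per
#' SNP id (`chrom:pos`); missing genotypes written as `NA`. SNP alleles are
#' carried in comment lines so the round trip is lossless.
#'
#' @param gm a [genotype_matrix()].
#' @param path file path.
#' @param labels optional labels passed through on read.
#' @return `read_genotype_tsv` returns a [genotype_matrix()].
#' @export
write_genotype_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("##snps\t", paste(
    paste(gm$snps$chrom, gm$snps$pos, gm$snps$ref, gm$snps$alt, sep = ":"),
    collapse = "\t")), con)
  writeLines(paste0("#sample_id\t", paste(snp_id(gm$snps), collapse = "\t")), con)
  utils::write.table(
    data.frame(sample_id = rownames(gm$g), gm$g, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path, labels = NULL) {
  first <- readLines(path, n = 2L)
  if (!startsWith(first[1L], "##snps\t")) stop("genotype TSV missing ##snps header")
  keys <- strsplit(sub("^##snps\t", "", first[1L]), "\t", fixed = TRUE)[[1L]]
  parts <- strsplit(keys, ":", fixed = TRUE)
  snps <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    ref = vapply(parts, `[`, "", 3L),
    alt = vapply(parts, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
  tab <- utils::read.table(path, sep = "\t", skip = 2L, stringsAsFactors = FALSE,
                           na.strings = "NA")
  g <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(g) <- tab[[1L]]
  genotype_matrix(g, snps, labels = labels)
}

#' Read a sample label file
#'
#' TSV with a `#`-prefixed header and columns `sample_id`, `pool_id`,
#' `subspecies`, `lineage`. When a [hierarchy_config()] is supplied, every
#' pool/subspecies/lineage is validated against it.
#'
#' @param path label TSV path.
#' @param hierarchy optional [hierarchy_config()] to validate classes against.
#' @return data.frame keyed by unique `sample_id`.
#' @export
read_labels <- function(path, hierarchy = NULL) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  need <- c("sample_id", "pool_id", "subspecies", "lineage")
  if (!all(need %in% cols)) {
    stop("label file must have columns: ", paste(need, collapse = ", "))
  }
  lab <- utils::read.table(path, sep = "\t", col.names = cols,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(lab$sample_id) > 0) {
    stop("duplicate sample_id in label file: ",
         lab$sample_id[duplicated(lab$sample_id)][1L])
  }
  if (!is.null(hierarchy)) {
    bad_pool <- setdiff(lab$pool_id, hierarchy$pools)
    bad_sub <- setdiff(lab$subspecies, hierarchy$subspecies)
    bad_lin <- setdiff(lab$lineage, hierarchy$lineages)
    if (length(c(bad_pool, bad_sub, bad_lin)) > 0) {
      stop("labels not in hierarchy: ",
           paste(c(bad_pool, bad_sub, bad_lin), collapse = ", "))
    }
  }
  lab[, need]
}

#' Write a sample label file
#'
#' @param labels data.frame with `sample_id`, `pool_id`, `subspecies`,
#'   `lineage`.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  con <- file(path, "w")
  on.exit(close(con))
  need <- c("sample_id", "pool_id", "subspecies", "lineage")
  writeLines(paste0("#", paste(need, collapse = "\t")), con)
  utils::write.table(labels[, need], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
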