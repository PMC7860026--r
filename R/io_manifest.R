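#' Panel manifest: the selected ancestry-informative SNP set
#'
#' One row per selected SNP, with the selection branch that picked it
#' (`pca_global`, `pca_<lineage>`, `fst_loose`, `fst_stringent`), the focal
#' unit it discriminates (a lineage for the PCA branch, a pool for the FST
#' branch, `global` at the top level) and the rank statistic it was
#' selected on (aggregate PC contribution or summed FST).
#'
#' @param entries data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `source`, `focal_unit`, `score`. SNP keys must be unique.
#' @param hierarchy optional [hierarchy_config()]; when given, every
#'   `focal_unit` must be `global`, a lineage or a pool of the hierarchy.
#' @return an object of class `panel_manifest` (a data.frame).
#' @export
panel_manifest <- function(entries, hierarchy = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "source", "focal_unit", "score")
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries) == 0L) {
    entries <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          source = character(), focal_unit = character(),
                          score = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(need %in% names(entries)))
  entries <- entries[, need]
  if (nrow(entries) > 0) {
    keys <- validate_snp_keys(entries[, c("chrom", "pos", "ref", "alt")])
    entries[, c("chrom", "pos", "ref", "alt")] <- keys
    ids <- snp_id(entries)
    if (anyDuplicated(ids) > 0) {
      stop("panel manifest: duplicate SNP key ", ids[duplicated(ids)][1L])
    }
    if (!is.null(hierarchy)) {
      units <- c("global", hierarchy$lineages, hierarchy$pools)
      bad <- setdiff(entries$focal_unit, units)
      if (length(bad) > 0) {
        stop("panel manifest: focal_unit not in hierarchy: ",
             paste(bad, collapse = ", "))
      }
    }
    entries$score <- as.numeric(entries$score)
  }
  rownames(entries) <- NULL
  class(entries) <- c("panel_manifest", "data.frame")
  entries
}

#' @export
print.panel_manifest <- function(x, ...) {
  cat("panel_manifest:", nrow(x), "SNPs\n")
  if (nrow(x) > 0) print(table(x$source))
  invisible(x)
}

#' Write / read a panel manifest TSV
#'
#' Tab-delimited with a `#`-prefixed header; round trip is lossless
#' (`read_panel_manifest(write_panel_manifest(x)) == x`). Duplicate SNP keys
#' are rejected on read.
#'
#' @param panel a [panel_manifest()].
#' @param path file path.
#' @param hierarchy optional [hierarchy_config()] for validation on read.
#' @return `read_panel_manifest` returns a [panel_manifest()].
#' @export
write_panel_manifest <- function(panel, path) {
  stopifnot(inherits(panel, "panel_manifest"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(panel), collapse = "\t")), con)
  if (nrow(panel) > 0) {
    utils::write.table(panel, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_panel_manifest
#' @export
read_panel_manifest <- function(path, hierarchy = NULL) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  body <- readLines(path)[-1L]
  if (length(body) == 0L) return(panel_manifest(data.frame()))
  tab <- utils::read.table(text = body, sep = "\t", col.names = cols,
                           stringsAsFactors = FALSE)
  panel_manifest(tab, hierarchy = hierarchy)
}

#' Subset a genotype matrix or pool table to a panel's SNPs
#'
#' @param x a [genotype_matrix()] or [pool_freq_table()].
#' @param panel a [panel_manifest()].
#' @return `x` restricted to the panel SNPs, in panel order.
#' @export
subset_to_panel <- function(x, panel) {
  stopifnot(inherits(panel, "panel_manifest"))
  ids <- snp_id(panel)
  if (inherits(x, "genotype_matrix")) {
    idx <- match(ids, snp_id(x$snps))
    if (anyNA(idx)) stop("panel SNP absent from genotype matrix: ", ids[is.na(idx)][1L])
    genotype_matrix(x$g[, idx, drop = FALSE], x$snps[idx, ], labels = x$labels)
  } else if (inherits(x, "pool_freq_table")) {
    idx <- match(ids, snp_id(x$snps))
    if (anyNA(idx)) stop("panel SNP absent from pool table: ", ids[is.na(idx)][1L])
    pool_freq_table(x$snps[idx, ], x$pools,
                    x$ref_depth[idx, , drop = FALSE],
                    x$alt_depth[idx, , drop = FALSE])
  } else {
    stop("unsupported object for subset_to_panel")
  }
}
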