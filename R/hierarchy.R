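#' Hierarchical population design for the simulator and panel selection
#'
#' A `hierarchy_config` describes a three-level population tree
#' (evolutionary lineage -> subspecies -> sequenced pool) together with the
#' per-level Balding-Nichols divergence parameters, the simulated marker and
#' sampling dimensions, and the per-level SNP selection quotas used by the
#' PCA branch.
#'
#' @param tree data.frame with columns `pool`, `subspecies`, `lineage`; one
#'   row per pool. Every pool belongs to exactly one subspecies and every
#'   subspecies to exactly one lineage.
#' @param f_lineage,f_subspecies,f_pool per-level divergence parameters
#'   (Wright's F), each in (0, 1). The defaults encode deep lineage
#'   divergence with shallow within-lineage differentiation.
#' @param n_snps number of simulated SNPs.
#' @param ancestral_freq_range length-2 numeric in (0,1): ancestral
#'   reference-allele frequencies are drawn uniformly from this range so that
#'   simulated sites segregate.
#' @param pool_coverage mean sequencing depth per pool per SNP (Poisson mean).
#' @param n_individuals_per_pool number of individually genotyped bees
#'   simulated per pool.
#' @param null_allele_rate per-subspecies probability that a SNP is a null
#'   allele (produces no genotype signal) in that subspecies. Either a single
#'   number applied to all subspecies or a named vector keyed by subspecies.
#' @param quotas named list of per-level SNP quotas for the PCA selection
#'   branch: a `global` count plus one count per lineage (lineages with a
#'   single pool cannot be analysed within-lineage and must have quota 0).
#'
#' @return an object of class `hierarchy_config`.
#' @seealso [honeybee_hierarchy()] for the 22-pool reference design.
#' @export
hierarchy_config <- function(tree,
                             f_lineage = 0.15,
                             f_subspecies = 0.05,
                             f_pool = 0.02,
                             n_snps = 20000L,
                             ancestral_freq_range = c(0.05, 0.95),
                             pool_coverage = 50,
                             n_individuals_per_pool = 90L,
                             null_allele_rate = 0.13,
                             quotas = NULL) {
  stopifnot(is.data.frame(tree), all(c("pool", "subspecies", "lineage") %in% names(tree)))
  tree <- data.frame(
    pool = as.character(tree$pool),
    subspecies = as.character(tree$subspecies),
    lineage = as.character(tree$lineage),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(tree$pool) > 0) {
    stop("hierarchy tree: pool ids must be unique")
  }
  sub2lin <- unique(tree[, c("subspecies", "lineage")])
  if (anyDuplicated(sub2lin$subspecies) > 0) {
    stop("hierarchy tree: each subspecies must belong to exactly one lineage")
  }
  for (f in c(f_lineage = f_lineage, f_subspecies = f_subspecies, f_pool = f_pool)) {
    if (!is.numeric(f) || length(f) != 1L || f <= 0 || f >= 1) {
      stop("divergence parameters must be single numbers in (0, 1)")
    }
  }
  if (length(ancestral_freq_range) != 2L ||
      ancestral_freq_range[1] >= ancestral_freq_range[2] ||
      ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1) {
    stop("ancestral_freq_range must be (lo, hi) with 0 < lo < hi < 1")
  }
  n_snps <- as.integer(n_snps)
  n_individuals_per_pool <- as.integer(n_individuals_per_pool)
  if (n_snps < 1L || n_individuals_per_pool < 1L || pool_coverage <= 0) {
    stop("n_snps, n_individuals_per_pool and pool_coverage must be >= 1")
  }
  subspecies <- unique(tree$subspecies)
  if (length(null_allele_rate) == 1L && is.null(names(null_allele_rate))) {
    null_allele_rate <- stats::setNames(rep(null_allele_rate, length(subspecies)), subspecies)
  } else {
    missing_sub <- setdiff(subspecies, names(null_allele_rate))
    if (length(missing_sub) > 0) {
      stop("null_allele_rate missing for subspecies: ", paste(missing_sub, collapse = ", "))
    }
    null_allele_rate <- null_allele_rate[subspecies]
  }
  if (any(null_allele_rate < 0 | null_allele_rate >= 1)) {
    stop("null_allele_rate values must be in [0, 1)")
  }
  lineages <- unique(tree$lineage)
  if (is.null(quotas)) {
    quotas <- c(list(global = 0L), stats::setNames(as.list(rep(0L, length(lineages))), lineages))
  }
  if (is.null(quotas$global)) quotas$global <- 0L
  pools_per_lineage <- table(tree$lineage)
  for (lin in lineages) {
    if (is.null(quotas[[lin]])) quotas[[lin]] <- 0L
    if (pools_per_lineage[[lin]] < 2L && quotas[[lin]] > 0L) {
      stop("lineage '", lin, "' has a single pool; its within-lineage quota must be 0")
    }
  }
  if (any(unlist(quotas) < 0)) stop("quotas must be >= 0")
  structure(
    list(
      tree = tree,
      lineages = lineages,
      subspecies = subspecies,
      pools = tree$pool,
      f_lineage = f_lineage,
      f_subspecies = f_subspecies,
      f_pool = f_pool,
      n_snps = n_snps,
      ancestral_freq_range = as.numeric(ancestral_freq_range),
      pool_coverage = pool_coverage,
      n_individuals_per_pool = n_individuals_per_pool,
      null_allele_rate = null_allele_rate,
      quotas = lapply(quotas, as.integer)
    ),
    class = "hierarchy_config"
  )
}

#' @export
print.hierarchy_config <- function(x, ...) {
  cat("hierarchy_config:", length(x$lineages), "lineages,",
      length(x$subspecies), "subspecies,", length(x$pools), "pools\n")
  cat("  F (lineage/subspecies/pool):",
      x$f_lineage, "/", x$f_subspecies, "/", x$f_pool, "\n")
  cat("  ", x$n_snps, "SNPs, coverage", x$pool_coverage, "x,",
      x$n_individuals_per_pool, "bees/pool\n")
  q <- unlist(x$quotas)
  cat("  PCA quotas:", paste(names(q), q, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Reference 22-pool European honey bee sampling design
#'
#' The reference design used throughout: 22 sequenced pools covering 14
#' subspecies (or genetic origins) nested in the four European evolutionary
#' lineages A, C, M and O, with the per-level PCA quotas used for panel
#' design (300 SNPs separating the lineages, then 1100 / 200 / 600 SNPs
#' within the C, M and O lineages; the A lineage contributes a single pool
#' and gets no within-lineage PCA quota).
#'
#' @param quotas per-level PCA quotas (default: the reference design's
#'   300/1100/200/600).
#' @param ... overrides passed on to [hierarchy_config()] (e.g. `n_snps`,
#'   `n_individuals_per_pool`).
#' @return a `hierarchy_config`.
#' @export
honeybee_hierarchy <- function(quotas = list(global = 300L, A = 0L, C = 1100L,
                                             M = 200L, O = 600L), ...) {
  tree <- data.frame(
    pool = c(
      "rut_mlt",
      "ada_grc", "car_aut_hun", "car_svn_hrv", "carp_rou_mda", "cec_grc",
      "lig_ita", "mac_mkd_grc", "rod_bgr",
      "ibe_esp_west_prt", "ibe_esp_eus", "ibe_esp_north", "ibe_esp_south",
      "mel_dnk", "mel_irl", "mel_imn", "mel_rus", "mel_che",
      "ana_tur", "rem_arm", "cau_tur_geo", "cyp_cyp"
    ),
    subspecies = c(
      "ruttneri",
      "adami", "carnica", "carnica", "carpatica", "cecropia",
      "ligustica", "macedonica", "rodopica",
      "iberiensis", "iberiensis", "iberiensis", "iberiensis",
      "mellifera", "mellifera", "mellifera", "mellifera", "mellifera",
      "anatoliaca", "remipes", "caucasia", "cypria"
    ),
    lineage = c(
      "A",
      rep("C", 8),
      rep("M", 9),
      rep("O", 4)
    ),
    stringsAsFactors = FALSE
  )
  hierarchy_config(tree, quotas = quotas, ...)
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' Pipeline stages (simulation, split, cross-validation, model fitting, ...)
#' each draw their own seed from the run's single master seed so that any
#' stage can be re-run in isolation and reproduce its output exactly.
#'
#' @param seed master seed (integer).
#' @param stage character tag of the stage.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * (seq_len(nchar(stage)) %% 7 + 1))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% (2^31 - 1))
}

# internal: map subspecies -> lineage as a named character vector
subspecies_lineage_map <- function(config) {
  sub2lin <- unique(config$tree[, c("subspecies", "lineage")])
  stats::setNames(sub2lin$lineage, sub2lin$subspecies)
}
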