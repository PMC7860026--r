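#' Confusion matrix with unassigned bookkeeping
#'
#' Rows are true classes, columns predicted classes. Predictions carrying
#' the unassigned label are excluded from the count matrix and tallied per
#' true class, so the percentage view is computed over assigned samples
#' only — exactly the bookkeeping a rejection threshold induces. The
#' conservation identity (assigned counts + unassigned = samples per true
#' class) always holds.
#'
#' @param truth character vector of true classes.
#' @param predicted character vector of predictions, possibly containing
#'   `unassigned_label`.
#' @param classes ordered class list (default: sorted union of observed
#'   classes).
#' @param unassigned_label the rejection label (default `"unassigned"`).
#' @return object of class `confusion_matrix`: `counts` (true x predicted),
#'   `percent` (row percentages over assigned, 1 decimal), `unassigned`
#'   (per true class), `classes`.
#' @export
confusion <- function(truth, predicted, classes = NULL,
                      unassigned_label = "unassigned") {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length")
  }
  if (is.null(classes)) {
    classes <- sort(unique(c(truth, setdiff(predicted, unassigned_label))))
  }
  bad <- setdiff(c(truth, predicted), c(classes, unassigned_label))
  if (length(bad) > 0) stop("labels outside the class set: ", paste(bad, collapse = ", "))
  is_un <- predicted == unassigned_label
  counts <- table(factor(truth[!is_un], levels = classes),
                  factor(predicted[!is_un], levels = classes))
  counts <- matrix(counts, nrow = length(classes),
                   dimnames = list(true = classes, predicted = classes))
  unassigned <- table(factor(truth[is_un], levels = classes))
  unassigned <- stats::setNames(as.integer(unassigned), classes)
  rs <- rowSums(counts)
  percent <- counts / ifelse(rs > 0, rs, NA_real_) * 100
  structure(
    list(counts = counts, percent = round(percent, 1),
         unassigned = unassigned, classes = classes,
         n_total = length(truth)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix:", x$n_total, "samples,", length(x$classes), "classes,",
      sum(x$unassigned), "unassigned\n")
  print(x$percent)
  invisible(x)
}

#' Accuracy statistics from a confusion matrix
#'
#' Reports correctly assigned and misclassified percentages with explicit
#' denominators: `of_total` divides by all samples, `of_assigned` divides
#' by assigned samples only (the denominator a rejection threshold makes
#' natural). Per-class accuracy is over that class's assigned samples.
#'
#' @param cm a [confusion()] result.
#' @return list: `n_total`, `n_assigned`, `n_unassigned`, `n_correct`,
#'   `n_misclassified`, `accuracy_of_total`, `misclassified_of_total`,
#'   `accuracy_of_assigned`, `misclassified_of_assigned` (percentages),
#'   `per_class` (named vector, % over assigned).
#' @export
accuracy_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n_assigned <- sum(cm$counts)
  if (cm$n_total == 0L) stop("empty confusion matrix")
  n_correct <- sum(diag(cm$counts))
  n_mis <- n_assigned - n_correct
  rs <- rowSums(cm$counts)
  per_class <- ifelse(rs > 0, diag(cm$counts) / rs * 100, NA_real_)
  list(
    n_total = cm$n_total,
    n_assigned = n_assigned,
    n_unassigned = sum(cm$unassigned),
    n_correct = n_correct,
    n_misclassified = n_mis,
    accuracy_of_total = 100 * n_correct / cm$n_total,
    misclassified_of_total = 100 * n_mis / cm$n_total,
    accuracy_of_assigned = if (n_assigned > 0) 100 * n_correct / n_assigned else NA_real_,
    misclassified_of_assigned = if (n_assigned > 0) 100 * n_mis / n_assigned else NA_real_,
    per_class = stats::setNames(per_class, cm$classes)
  )
}

#' Collapse subspecies predictions to their evolutionary lineage
#'
#' Within-lineage confusions (e.g. between two C-lineage subspecies) become
#' correct at lineage level, so lineage accuracy is always at least
#' subspecies accuracy. The unassigned label is preserved.
#'
#' @param predictions character vector of subspecies labels (may contain
#'   the unassigned label).
#' @param lineage_map named character vector subspecies -> lineage, e.g.
#'   from [hierarchy_config()] via its tree.
#' @param unassigned_label rejection label to pass through.
#' @return character vector of lineage labels.
#' @export
collapse_to_lineage <- function(predictions, lineage_map,
                                unassigned_label = "unassigned") {
  out <- predictions
  keep <- predictions != unassigned_label
  mapped <- lineage_map[predictions[keep]]
  if (anyNA(mapped)) {
    stop("no lineage mapping for class: ",
         predictions[keep][is.na(mapped)][1L])
  }
  out[keep] <- mapped
  out
}

#' Sweep the rejection threshold
#'
#' For each threshold, samples are assigned by argmax when the top
#' probability reaches the threshold, and the table reports the assigned
#' fraction and the accuracy / misclassification among assigned samples.
#' The count identity assigned + unassigned = total holds in every row;
#' the assigned fraction is non-increasing in the threshold.
#'
#' @param probs probability matrix ([predict_probabilities()]).
#' @param truth true class labels.
#' @param thresholds numeric grid in \[0, 1\].
#' @return data.frame: `threshold`, `n_assigned`, `n_unassigned`,
#'   `assigned_fraction`, `accuracy_of_assigned`,
#'   `misclassified_of_assigned` (percent; NA when nothing is assigned).
#' @export
threshold_sweep <- function(probs, truth, thresholds = seq(0, 1, by = 0.05)) {
  stopifnot(nrow(probs) == length(truth))
  if (any(thresholds < 0 | thresholds > 1)) stop("thresholds must be in [0, 1]")
  best <- max.col(probs, ties.method = "first")
  best_class <- colnames(probs)[best]
  p <- probs[cbind(seq_len(nrow(probs)), best)]
  rows <- lapply(thresholds, function(tau) {
    assigned <- p >= tau
    n_a <- sum(assigned)
    correct <- sum(best_class[assigned] == truth[assigned])
    data.frame(
      threshold = tau,
      n_assigned = n_a,
      n_unassigned = length(truth) - n_a,
      assigned_fraction = n_a / length(truth),
      accuracy_of_assigned = if (n_a > 0) 100 * correct / n_a else NA_real_,
      misclassified_of_assigned = if (n_a > 0) 100 * (n_a - correct) / n_a else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Call rate per sample and per class
#'
#' Fraction of non-missing genotypes per sample, with class means over the
#' labeled subspecies — the statistic null alleles depress in a
#' subspecies-specific way.
#'
#' @param gm a [genotype_matrix()].
#' @return list: `per_sample` (named vector), `per_class` (named vector of
#'   subspecies means, NULL when unlabeled), `overall`.
#' @export
call_rate <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  per_sample <- rowMeans(!is.na(gm$g))
  per_class <- NULL
  if (!is.null(gm$labels)) {
    per_class <- tapply(per_sample, gm$labels$subspecies, mean)
    per_class <- stats::setNames(as.numeric(per_class), names(per_class))
  }
  list(per_sample = per_sample, per_class = per_class,
       overall = mean(per_sample))
}

#' Two-dimensional embedding of samples
#'
#' Classical metric multidimensional scaling (principal coordinates) of the
#' pairwise sample distances, for visual inspection of population
#' structure and mislabeled samples. Deterministic given the input;
#' identical samples land on coincident points, well-separated classes on
#' separated clusters.
#'
#' @param x feature matrix (e.g. [one_hot_encode()] output) or a
#'   [genotype_matrix()] (then Hamming distance over genotype states,
#'   missing matching nothing, is used).
#' @param seed integer seed, recorded for provenance (the embedding itself
#'   has no random component).
#' @return numeric matrix (samples x 2) of coordinates.
#' @export
embed_2d <- function(x, seed = 1L) {
  if (inherits(x, "genotype_matrix")) {
    d <- genotype_hamming(x$g)
    ids <- rownames(x$g)
  } else {
    x <- as.matrix(x)
    d <- stats::dist(x)
    ids <- rownames(x)
  }
  n <- attr(d, "Size")
  if (n < 3L) stop("need at least 3 samples to embed")
  set.seed(as.integer(seed))
  coords <- stats::cmdscale(d, k = 2L)
  # cmdscale may return fewer axes for degenerate inputs; pad with zeros
  if (ncol(coords) < 2L) {
    coords <- cbind(coords, matrix(0, nrow = n, ncol = 2L - ncol(coords)))
  }
  dimnames(coords) <- list(ids, c("dim1", "dim2"))
  coords
}

# internal: Hamming distance between genotype rows; a missing value matches
# nothing (not even another missing value)
genotype_hamming <- function(g) {
  n <- nrow(g)
  d <- matrix(0, n, n)
  states <- list(g == 0L, g == 1L, g == 2L)
  match_counts <- matrix(0, n, n)
  for (s in states) {
    s[is.na(s)] <- FALSE
    match_counts <- match_counts + tcrossprod(s)
  }
  d <- ncol(g) - match_counts
  diag(d) <- 0
  stats::as.dist(d)
}

#' Flag samples whose neighbors disagree with their label
#'
#' Automated stand-in for visual outlier screening: a sample is flagged
#' when the majority label among its k nearest neighbors (Hamming distance
#' over genotype states, missing matching nothing, self excluded) differs
#' from its own label. Deterministic; neighbor ties at the distance cutoff
#' are resolved by sample order.
#'
#' @param gm a labeled [genotype_matrix()].
#' @param labels character vector of class labels (default: the matrix's
#'   subspecies labels).
#' @param k neighborhood size (default 10; must be < n_samples).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flag_label_outliers <- function(gm, labels = NULL, k = 10L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(labels)) {
    if (is.null(gm$labels)) stop("no labels supplied or stored")
    labels <- gm$labels$subspecies
  }
  n <- nrow(gm$g)
  if (k >= n) stop("k must be smaller than the number of samples")
  d <- as.matrix(genotype_hamming(gm$g))
  flagged <- character(0)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])
    nn <- (seq_len(n)[-i])[ord][seq_len(k)]
    tab <- sort(table(labels[nn]), decreasing = TRUE)
    if (names(tab)[1L] != labels[i]) {
      flagged <- c(flagged, rownames(gm$g)[i])
    }
  }
  flagged
}
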