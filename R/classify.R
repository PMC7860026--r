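#' One-hot encode genotypes for supervised learning
#'
#' Each SNP expands to a block of four binary indicators —
#' hom-ref, het, hom-alt, missing — with exactly one indicator active per
#' sample. Missingness is deliberately its own state rather than being
#' imputed: null alleles are systematically absent in particular
#' subspecies, so the missing indicator carries real ancestry signal.
#' Column order is deterministic (SNP order x state order).
#'
#' @param gm a [genotype_matrix()].
#' @return numeric matrix samples x (4 * n_snps); column names are
#'   `<chrom:pos>|<state>`.
#' @export
one_hot_encode <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$g
  n <- nrow(g)
  p <- ncol(g)
  code <- g
  code[is.na(code)] <- 3L
  x <- matrix(0, n, 4L * p)
  x[cbind(rep(seq_len(n), p),
          rep((seq_len(p) - 1L) * 4L, each = n) + as.vector(code) + 1L)] <- 1
  states <- c("hom_ref", "het", "hom_alt", "missing")
  colnames(x) <- paste(rep(snp_id(gm$snps), each = 4L), rep(states, p), sep = "|")
  rownames(x) <- rownames(g)
  x
}

#' Shuffled train/test split of the reference samples
#'
#' Seeded shuffle then a floor(fraction * n) training cut, so a 70/30 split
#' of 1988 reference samples yields 1391 training and 597 test samples.
#' The two sets partition the input (disjoint and exhaustive).
#'
#' @param sample_ids character vector of sample ids (n >= 2).
#' @param train_fraction fraction in (0, 1), default 0.7.
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_reference <- function(sample_ids, train_fraction = 0.7, seed) {
  n <- length(sample_ids)
  if (n < 2L) stop("need at least 2 samples to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  set.seed(as.integer(seed))
  shuffled <- sample(sample_ids)
  n_train <- floor(train_fraction * n)
  list(train = shuffled[seq_len(n_train)], test = shuffled[-seq_len(n_train)])
}

#' Candidate classifier specifications
#'
#' The model-comparison slate: linear support vector classifier, RBF-kernel
#' SVM, multinomial (ridge-regularized) logistic regression, and random
#' forest. Every candidate honours the same contract —
#' `fit(x, y, seed, probability)` then `predict_class` / `predict_prob` —
#' so the slate is pluggable. Margin-based SVMs obtain class probabilities
#' by cross-validated Platt scaling fitted on the training data only
#' (the `probability = TRUE` machinery of the underlying implementation).
#'
#' @param names which candidates to return (default: all four).
#' @return named list of candidate specs.
#' @export
candidate_models <- function(names = c("linear_svc", "svm_rbf",
                                       "logistic", "random_forest")) {
  all <- list(
    linear_svc = list(
      fit = function(x, y, seed, probability = TRUE) {
        fit_ovr_svm(x, y, kernel = "linear", seed = seed,
                    probability = probability)
      },
      predict_class = function(m, x) ovr_predict_class(m, x),
      predict_prob = function(m, x) ovr_predict_prob(m, x)
    ),
    svm_rbf = list(
      fit = function(x, y, seed, probability = TRUE) {
        fit_ovr_svm(x, y, kernel = "radial", seed = seed,
                    probability = probability)
      },
      predict_class = function(m, x) ovr_predict_class(m, x),
      predict_prob = function(m, x) ovr_predict_prob(m, x)
    ),
    logistic = list(
      fit = function(x, y, seed, probability = TRUE) {
        set.seed(seed)
        glmnet::glmnet(x, factor(y), family = "multinomial", alpha = 0,
                       lambda = 1e-3, standardize = FALSE)
      },
      predict_class = function(m, x) {
        drop(stats::predict(m, x, type = "class"))
      },
      predict_prob = function(m, x) {
        pr <- stats::predict(m, x, type = "response")
        matrix(pr, nrow = nrow(x), dimnames = dimnames(pr)[1:2])
      }
    ),
    random_forest = list(
      fit = function(x, y, seed, probability = TRUE) {
        ranger::ranger(x = x, y = factor(y), probability = TRUE,
                       num.trees = 300L, seed = seed, num.threads = 1L)
      },
      predict_class = function(m, x) {
        pr <- stats::predict(m, data = x, num.threads = 1L)$predictions
        colnames(pr)[max.col(pr, ties.method = "first")]
      },
      predict_prob = function(m, x) {
        stats::predict(m, data = x, num.threads = 1L)$predictions
      }
    )
  )
  all[match.arg(names, names(all), several.ok = TRUE)]
}

# ---- one-vs-rest SVM with cross-validated Platt calibration ----
#
# A multiclass support vector classifier built as one binary margin
# classifier per class (one-vs-rest). Class probabilities come from Platt
# scaling: a per-class sigmoid p = plogis(b0 + b1 * score) fitted to
# OUT-OF-FOLD decision scores (5-fold, stratified, seeded), so the
# calibration never sees the scores of the machine that produced them.
# Platt's smoothed targets ((n+ + 1)/(n+ + 2) and 1/(n- + 2)) keep the
# sigmoid finite even when the training classes are perfectly separable.

fit_ovr_svm <- function(x, y, kernel, seed, probability = TRUE,
                        n_calib_folds = 5L) {
  classes <- sort(unique(y))
  set.seed(seed)
  fit_binaries <- function(xx, yy) {
    lapply(classes, function(cls) {
      yb <- factor(ifelse(yy == cls, "pos", "neg"), levels = c("pos", "neg"))
      m <- e1071::svm(x = xx, y = yb, kernel = kernel, scale = FALSE)
      # e1071 orients decision values by first label seen in the data, not
      # by factor level; read the orientation off a probe prediction
      probe <- stats::predict(m, xx[1L, , drop = FALSE], decision.values = TRUE)
      orient <- colnames(attr(probe, "decision.values"))[1L]
      list(model = m, sign = if (identical(orient, "pos/neg")) 1 else -1)
    })
  }
  calibration <- NULL
  if (probability) {
    k <- min(n_calib_folds, min(table(y)))
    if (k < 2L) k <- 2L
    fold <- stratified_folds(y, k, stage_seed(seed, "platt_folds"))
    oof <- matrix(NA_real_, nrow(x), length(classes))
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < length(classes)) next
      ms <- fit_binaries(x[tr, , drop = FALSE], y[tr])
      oof[!tr, ] <- ovr_scores(ms, x[!tr, , drop = FALSE])
    }
    calibration <- lapply(seq_along(classes), function(ci) {
      pos <- y == classes[ci]
      ok <- !is.na(oof[, ci])
      s <- oof[ok, ci]
      n_pos <- sum(pos[ok]); n_neg <- sum(!pos[ok])
      target <- ifelse(pos[ok], (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
      fit <- suppressWarnings(
        stats::glm(target ~ s, family = stats::quasibinomial()))
      stats::coef(fit)
    })
  }
  structure(list(binaries = fit_binaries(x, y), classes = classes,
                 kernel = kernel, calibration = calibration),
            class = "ovr_svm")
}

ovr_scores <- function(binaries, x) {
  vapply(binaries, function(b) {
    pr <- stats::predict(b$model, x, decision.values = TRUE)
    b$sign * drop(attr(pr, "decision.values"))
  }, numeric(nrow(x)))
}

ovr_predict_class <- function(m, x) {
  s <- matrix(ovr_scores(m$binaries, x), nrow = nrow(x))
  m$classes[max.col(s, ties.method = "first")]
}

ovr_predict_prob <- function(m, x) {
  if (is.null(m$calibration)) stop("model was fitted without calibration")
  s <- matrix(ovr_scores(m$binaries, x), nrow = nrow(x))
  pr <- vapply(seq_along(m$classes), function(ci) {
    b <- m$calibration[[ci]]
    stats::plogis(b[1L] + b[2L] * s[, ci])
  }, numeric(nrow(x)))
  pr <- matrix(pr, nrow = nrow(x), dimnames = list(rownames(x), m$classes))
  # degenerate all-zero rows (no class claims the sample) -> uniform
  zero <- rowSums(pr) < .Machine$double.eps
  pr[zero, ] <- 1 / ncol(pr)
  pr / rowSums(pr)
}

# internal: stratified fold assignment (one fold id per sample)
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Compare candidate classifiers by stratified k-fold cross-validation
#'
#' Each candidate is scored by mean and SD of its fold accuracies under a
#' shared stratified fold assignment. The best model is the one with the
#' highest mean accuracy; ties go to the lowest SD. If some class has fewer
#' samples than `k_folds`, the fold count degrades to the smallest class
#' size (minimum 2) with a warning.
#'
#' @param candidates named list from [candidate_models()].
#' @param x feature matrix (from [one_hot_encode()]).
#' @param y character vector of class labels.
#' @param k_folds folds (default 10).
#' @param seed integer seed (folds and per-fold fits).
#' @return data.frame with one row per candidate (`model`, `mean_accuracy`,
#'   `sd_accuracy`, `k_folds`) sorted best first, with the winner's name in
#'   attribute `"best"`.
#' @export
evaluate_candidates <- function(candidates, x, y, k_folds = 10L, seed) {
  stopifnot(length(y) == nrow(x), length(candidates) >= 1L)
  min_class <- min(table(y))
  k <- k_folds
  if (min_class < k_folds) {
    k <- max(2L, min_class)
    warning("smallest class has ", min_class, " samples; using ", k, " folds")
  }
  fold <- stratified_folds(y, k, stage_seed(seed, "cv_folds"))
  rows <- lapply(names(candidates), function(nm) {
    spec <- candidates[[nm]]
    acc <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      m <- spec$fit(x[tr, , drop = FALSE], y[tr],
                    seed = stage_seed(seed, paste0("cv_", nm, "_", f)),
                    probability = FALSE)
      mean(spec$predict_class(m, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    data.frame(model = nm, mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
               k_folds = k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_accuracy, out$sd_accuracy), ]
  rownames(out) <- NULL
  attr(out, "best") <- out$model[1L]
  out
}

#' Fit the chosen classifier on the training set
#'
#' Trains the candidate on the full training data (with probability
#' calibration enabled) and records everything needed to apply it safely
#' later: class order, feature layout, candidate name and seed.
#'
#' @param candidate candidate name (see [candidate_models()]) or a single
#'   spec from it.
#' @param x training feature matrix.
#' @param y training labels (>= 2 classes).
#' @param seed integer seed.
#' @return an object of class `aim_model`.
#' @export
fit_classifier <- function(candidate, x, y, seed) {
  if (is.character(candidate)) {
    name <- candidate
    spec <- candidate_models(candidate)[[1L]]
  } else {
    name <- attr(candidate, "name") %||% "custom"
    spec <- candidate
  }
  if (length(unique(y)) < 2L) stop("training set must contain at least 2 classes")
  if (length(y) != nrow(x) || nrow(x) == 0L) stop("empty or mismatched training set")
  model <- spec$fit(x, y, seed = seed, probability = TRUE)
  structure(
    list(name = name, spec = spec, model = model,
         classes = sort(unique(y)), features = colnames(x), seed = seed,
         n_train = nrow(x), version = 1L),
    class = "aim_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.aim_model <- function(x, ...) {
  cat("aim_model:", x$name, "|", length(x$classes), "classes |",
      length(x$features), "features |", x$n_train, "training samples\n")
  invisible(x)
}

#' Predict calibrated class probabilities
#'
#' Returns the samples x classes probability table, columns in the model's
#' fixed class order, rows renormalized to sum to exactly 1. The feature
#' layout of `x` must match the training layout; on mismatch the error
#' names the first offending SNP block.
#'
#' @param model an [fit_classifier()] model.
#' @param x feature matrix with the training column layout.
#' @return numeric matrix (samples x classes), rows summing to 1.
#' @export
predict_probabilities <- function(model, x) {
  stopifnot(inherits(model, "aim_model"))
  if (is.null(colnames(x)) || length(colnames(x)) != length(model$features) ||
      any(colnames(x) != model$features)) {
    bad <- if (is.null(colnames(x))) "(unnamed columns)" else {
      i <- which(colnames(x)[seq_len(min(ncol(x), length(model$features)))] !=
                 model$features[seq_len(min(ncol(x), length(model$features)))])
      if (length(i) > 0) sub("\\|.*$", "", colnames(x)[i[1L]]) else "(column count)"
    }
    stop("feature layout mismatch at SNP block ", bad)
  }
  pr <- model$spec$predict_prob(model$model, x)
  pr <- pr[, model$classes, drop = FALSE]
  pr <- pr / rowSums(pr)
  rownames(pr) <- rownames(x)
  pr
}

#' Assign samples from a probability table with a rejection threshold
#'
#' The predicted class is the argmax of each row (ties broken by class
#' order); a sample whose maximum probability falls below the threshold is
#' left `unassigned` rather than forced into a class.
#'
#' @param probs probability matrix from [predict_probabilities()].
#' @param threshold rejection threshold tau in \[0, 1\] (default 0.90).
#' @param unassigned_label label for rejected samples.
#' @return data.frame: `sample_id`, `predicted` (class or the unassigned
#'   label), `best_class`, `probability`.
#' @export
assign_samples <- function(probs, threshold = 0.90,
                           unassigned_label = "unassigned") {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  best <- max.col(probs, ties.method = "first")
  best_class <- colnames(probs)[best]
  p <- probs[cbind(seq_len(nrow(probs)), best)]
  data.frame(
    sample_id = rownames(probs) %||% paste0("sample", seq_len(nrow(probs))),
    predicted = ifelse(p >= threshold, best_class, unassigned_label),
    best_class = best_class,
    probability = p,
    stringsAsFactors = FALSE
  )
}

#' Persist / restore a fitted model
#'
#' The artifact carries the class order, feature layout, calibration and
#' seed, so a reloaded model reproduces its predictions exactly.
#'
#' @param model an `aim_model`.
#' @param path file path (RDS).
#' @return `load_model` returns the `aim_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "aim_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "aim_model")) stop("not an aim_model artifact")
  model
}
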