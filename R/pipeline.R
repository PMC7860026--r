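#' Run the full panel-design and assignment pipeline on simulated data
#'
#' Convenience orchestration used by the command-line tool and the test
#' suite: simulate a hierarchical dataset, build the two-branch marker
#' panel, restrict genotypes to the panel, one-hot encode, split 70/30,
#' pick the best candidate by stratified cross-validation, fit it, predict
#' calibrated probabilities for the held-out samples and assign with the
#' rejection threshold. Every stage draws its seed from the single master
#' seed via [stage_seed()].
#'
#' @param config a [hierarchy_config()].
#' @param seed master seed.
#' @param quotas PCA quotas (default `config$quotas`).
#' @param k_loose,k_stringent per-pool FST quotas.
#' @param candidates candidate names for [candidate_models()].
#' @param k_folds cross-validation folds.
#' @param train_fraction training fraction of the reference samples.
#' @param threshold rejection threshold for assignment.
#' @return list with `sim`, `panel`, `cv` (candidate comparison), `model`,
#'   `split`, `probs`, `assignments` (held-out samples), `truth_test`
#'   (their true subspecies), and `confusion` / `report` at the chosen
#'   threshold.
#' @export
run_pipeline <- function(config, seed,
                         quotas = NULL,
                         k_loose = 20L, k_stringent = 80L,
                         candidates = c("linear_svc", "logistic"),
                         k_folds = 10L,
                         train_fraction = 0.7,
                         threshold = 0.90) {
  sim <- simulate_dataset(config, seed = stage_seed(seed, "simulate"))
  panel <- build_panel(sim$pool_table, config, quotas = quotas,
                       k_loose = k_loose, k_stringent = k_stringent)
  gm <- subset_to_panel(sim$genotypes, panel)
  x <- one_hot_encode(gm)
  y <- stats::setNames(gm$labels$subspecies, gm$labels$sample_id)
  split <- split_reference(rownames(x), train_fraction = train_fraction,
                           seed = stage_seed(seed, "split"))
  cv <- evaluate_candidates(candidate_models(candidates),
                            x[split$train, , drop = FALSE],
                            unname(y[split$train]),
                            k_folds = k_folds, seed = stage_seed(seed, "cv"))
  model <- fit_classifier(attr(cv, "best"),
                          x[split$train, , drop = FALSE],
                          unname(y[split$train]),
                          seed = stage_seed(seed, "fit"))
  probs <- predict_probabilities(model, x[split$test, , drop = FALSE])
  assignments <- assign_samples(probs, threshold = threshold)
  truth_test <- unname(y[split$test])
  cm <- confusion(truth_test, assignments$predicted, classes = model$classes)
  list(sim = sim, panel = panel, cv = cv, model = model, split = split,
       probs = probs, assignments = assignments, truth_test = truth_test,
       confusion = cm, report = accuracy_report(cm))
}
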