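#' End-to-end study pipeline on a synthetic cohort
#'
#' Runs the full analysis from a single configuration and seed:
#' simulate a cohort from a structural causal model, generate morphometric
#' features, predict brain age under age-stratified cross-validation with
#' per-fold age-bias correction, compute the brain age gap (BAG),
#' discretize with the clinical scheme, learn the constrained network
#' structure, select the pruning threshold by cross-validated AUC, fit the
#' final Bayesian network on the full table, validate it, and produce the
#' observation-vs-intervention tables and edge-sign labels.
#'
#' By default the morphometric features track each subject's effective
#' brain age (chronological age plus the generating model's true BAG), so
#' the BAG computed by the brain-age stage carries the simulated
#' risk-factor signal downstream; set `morph_on_brain_age = FALSE` to make
#' features depend on chronological age only.
#'
#' @param n cohort size (default 2025).
#' @param seed master integer seed; all stage seeds derive from it.
#' @param scm generating [scm_spec()] (default [default_study_scm()]).
#' @param k CV folds for the brain-age stage (default 10).
#' @param config [regressor_config()] for the brain-age network.
#' @param search_architectures if TRUE, run [select_architecture()] over
#'   all four candidates first (slower); default FALSE uses `config`.
#' @param morph list of overrides passed to [generate_morphometrics()]
#'   (e.g. `list(noise_sd = rep(0, 223))`).
#' @param morph_on_brain_age couple features to age + true BAG
#'   (default TRUE when the cohort has a BAG column).
#' @param l1_penalty L1 penalty for structure learning.
#' @param candidate_thresholds pruning-threshold grid.
#' @param cv_select list of [select_threshold()] CV options
#'   (default `repeats = 3` for the selection stage).
#' @param cv_final list: `k`, `repeats` for the final validation
#'   (default 10 x 10).
#' @param pseudo_count Dirichlet prior per cell.
#' @return object of class `bag_study` with the cohort, brain-age result,
#'   discretized table, weighted adjacency, threshold report, final model,
#'   CV report, observe-vs-intervene tables for the BAG's parents, and
#'   edge signs.
#' @export
run_study_pipeline <- function(n = 2025L, seed = 20220822L,
                               scm = default_study_scm(), k = 10L,
                               config = regressor_config(),
                               search_architectures = FALSE,
                               morph = list(),
                               morph_on_brain_age = TRUE,
                               l1_penalty = 0.1,
                               candidate_thresholds = c(0.05, 0.1, 0.15, 0.2, 0.3),
                               cv_select = list(repeats = 3L),
                               cv_final = list(k = 10L, repeats = 10L),
                               pseudo_count = 1) {
  if (seed > 2147483000) stop("run_study_pipeline: seed too large")
  seed <- as.integer(seed)
  cohort <- generate_scm_cohort(scm, n, seed = seed)
  true_bag <- cohort$BAG
  brain_age <- if (morph_on_brain_age && !is.null(true_bag))
    cohort$age + true_bag else NULL
  morph_args <- utils::modifyList(
    list(cohort = cohort, seed = seed + 1L, brain_age = brain_age), morph)
  features <- do.call(generate_morphometrics, morph_args)
  folds <- make_stratified_folds(cohort$age, k = k, seed = seed + 2L)
  if (search_architectures)
    config <- select_architecture(features, cohort$age, folds = folds,
                                  max_epochs = config$max_epochs,
                                  patience = config$patience,
                                  learning_rate = config$learning_rate,
                                  seed = config$seed)
  ba <- brain_age_pipeline(features, cohort$age, config, folds)
  cohort$true_BAG <- true_bag
  cohort$BAG <- ba$result$bag
  disc <- discretize_cohort(cohort)
  enc <- encode_for_structure_learning(cohort)
  constraints <- default_constraints(names(enc))
  W <- learn_weighted_adjacency(enc, constraints, l1_penalty = l1_penalty)
  sel_opts <- utils::modifyList(list(k = 10L, repeats = 3L,
                                     seed = seed + 3L,
                                     pseudo_count = pseudo_count),
                                cv_select)
  sel <- select_threshold(W, candidate_thresholds, disc, sel_opts)
  model <- fit_cpds(sel$dag, disc, pseudo_count = pseudo_count)
  cvf <- utils::modifyList(list(k = 10L, repeats = 10L), cv_final)
  cv_report <- crossvalidated_auc(sel$dag, disc, k = cvf$k,
                                  repeats = cvf$repeats, seed = seed + 4L,
                                  pseudo_count = pseudo_count)
  bag_parents <- dag_parents(sel$dag, "BAG")
  ovi <- lapply(bag_parents, function(rf)
    observe_vs_intervene_table(model, rf, "BAG"))
  names(ovi) <- bag_parents
  structure(list(
    cohort = cohort, features_dim = dim(features), folds = folds,
    config = config, brain_age = ba, discrete = disc,
    adjacency = W, threshold = sel$threshold,
    threshold_report = sel$report, dag = sel$dag, model = model,
    cv_report = cv_report, ovi = ovi,
    edge_signs = classify_all_edges(model),
    truth_dag = scm_dag(scm), seed = seed), class = "bag_study")
}

#' @export
print.bag_study <- function(x, ...) {
  cat("Brain-age-gap causal study (synthetic cohort, n =",
      nrow(x$cohort), ", seed", x$seed, ")\n")
  cat(sprintf("  brain age MAE: %.2f raw -> %.2f corrected (years)\n",
              x$brain_age$mae_raw, x$brain_age$mae_corrected))
  cat("  pruning threshold:", x$threshold, "->", nrow(x$dag$edges), "edges\n")
  cat(sprintf("  CV AUC: average %.3f, BAG %.3f\n", x$cv_report$average,
              x$cv_report$report$auc_mean[x$cv_report$report$node == "BAG"]))
  invisible(x)
}
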