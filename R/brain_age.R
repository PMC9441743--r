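#' Regressor configuration
#'
#' The candidate architectures are feed-forward networks with one to four
#' hidden layers: `(256)`, `(256, 128)`, `(256, 128, 64)` and
#' `(256, 128, 64, 32)` neurons. Inputs are z-scored with training-fold
#' statistics only; training uses full-batch Adam with early stopping on
#' validation MAE.
#'
#' @param hidden hidden-layer widths; must be one of the four candidates.
#' @param max_epochs maximum training epochs (default 500).
#' @param patience early-stopping patience on validation MAE (default 20).
#' @param learning_rate Adam step size (default 0.01).
#' @param seed integer seed for weight initialization.
#' @return an object of class `regressor_config`.
#' @export
regressor_config <- function(hidden = c(256L, 128L), max_epochs = 500L,
                             patience = 20L, learning_rate = 0.01,
                             seed = 1L) {
  cands <- candidate_architectures()
  ok <- any(vapply(cands, function(cc) identical(as.integer(hidden), cc),
                   logical(1)))
  if (!ok)
    stop("regressor_config: 'hidden' must be one of (256), (256,128), ",
         "(256,128,64), (256,128,64,32)")
  structure(list(hidden = as.integer(hidden), max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "regressor_config")
}

#' @rdname regressor_config
#' @export
candidate_architectures <- function() {
  list(256L, c(256L, 128L), c(256L, 128L, 64L), c(256L, 128L, 64L, 32L))
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features))
    features <- features[, setdiff(names(features), "subject_id"), drop = FALSE]
  X <- as.matrix(features)
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("features must be a numeric table with finite values")
  X
}

#' Cross-validated brain-age regression
#'
#' For each of the `k` folds, a network is trained on the remaining data
#' (minus an age-stratified validation split used only for early stopping)
#' and predicts the held-out fold, so every subject receives exactly one
#' out-of-fold prediction from a model that never saw it. Features are
#' z-scored per fold with training statistics; constant features are left
#' centred.
#'
#' @param features feature table (rows align with `ages`).
#' @param ages chronological ages in years.
#' @param config a [regressor_config()].
#' @param folds a [make_stratified_folds()] assignment over `ages`.
#' @return object of class `brain_age_fit`: `predicted` (out-of-fold raw
#'   predicted ages), and `per_fold` (roles and validation-set predictions
#'   per CV iteration, for downstream bias correction).
#' @export
train_regressor <- function(features, ages, config = regressor_config(),
                            folds) {
  X_all <- as_feature_matrix(features)
  if (nrow(X_all) != length(ages))
    stop("train_regressor: features and ages are misaligned")
  stopifnot(inherits(folds, "fold_assignment"), inherits(config, "regressor_config"))
  predicted <- rep(NA_real_, length(ages))
  per_fold <- vector("list", folds$k)
  for (f in 0:(folds$k - 1L)) {
    roles <- fold_roles(folds, ages, f)
    mu <- colMeans(X_all[roles$train, , drop = FALSE])
    sdv <- apply(X_all[roles$train, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    zs <- function(idx) sweep(sweep(X_all[idx, , drop = FALSE], 2L, mu), 2L, sdv, `/`)
    fit <- mlp_train(zs(roles$train), ages[roles$train],
                     zs(roles$validation), ages[roles$validation],
                     hidden = config$hidden,
                     learning_rate = config$learning_rate,
                     max_epochs = config$max_epochs,
                     patience = config$patience,
                     seed = config$seed + f)
    predicted[roles$test] <- mlp_predict(fit$par, zs(roles$test))
    per_fold[[f + 1L]] <- list(
      roles = roles,
      val_predicted = mlp_predict(fit$par, zs(roles$validation)),
      val_mae = fit$mae, epochs = fit$epoch)
  }
  structure(list(predicted = predicted, per_fold = per_fold,
                 config = config, folds = folds),
            class = "brain_age_fit")
}

#' Architecture selection by cross-validated MAE
#'
#' Evaluates each candidate architecture on the same fold splits and returns
#' the configuration with the lowest pooled out-of-fold MAE; ties break
#' toward the architecture with fewer parameters.
#'
#' @param features,ages,folds as in [train_regressor()].
#' @param candidates list of hidden-width vectors
#'   (default [candidate_architectures()]).
#' @param ... further arguments to [regressor_config()] (epochs, seed, ...).
#' @return the winning [regressor_config()], with the per-candidate MAEs in
#'   attribute `"report"`.
#' @export
select_architecture <- function(features, ages, candidates = candidate_architectures(),
                                folds, ...) {
  if (length(candidates) < 1L) stop("select_architecture: no candidates")
  maes <- npar <- numeric(length(candidates))
  n_in <- ncol(as_feature_matrix(features))
  for (i in seq_along(candidates)) {
    cfg <- regressor_config(hidden = candidates[[i]], ...)
    fit <- train_regressor(features, ages, cfg, folds)
    maes[i] <- mean(abs(fit$predicted - ages))
    sizes <- c(n_in, cfg$hidden, 1L)
    npar[i] <- sum(sizes[-length(sizes)] * sizes[-1L] + sizes[-1L])
  }
  best <- order(maes, npar)[1L]
  out <- regressor_config(hidden = candidates[[best]], ...)
  attr(out, "report") <- data.frame(
    architecture = vapply(candidates, paste, "", collapse = "-"),
    mae = maes, n_parameters = npar)
  out
}

#' Age-bias correction of brain-age predictions
#'
#' Brain-age models overestimate young and underestimate old subjects
#' (regression toward the mean). The systematic bias is summarized by the
#' least-squares line `PredictedAge = alpha * ChronologicalAge + beta`,
#' fitted on held-out (validation) data, and removed on test data by
#' `Corrected = Predicted + [Chronological - (Chronological * alpha + beta)]`.
#'
#' @param predicted predicted ages in years.
#' @param chronological chronological ages in years (at least two distinct
#'   values).
#' @return `fit_bias_correction`: object of class `bias_correction` with
#'   slope `alpha` (unitless) and intercept `beta` (years).
#' @export
fit_bias_correction <- function(predicted, chronological) {
  if (length(predicted) != length(chronological) || length(predicted) < 2L)
    stop("fit_bias_correction: need aligned vectors of length >= 2")
  if (stats::var(chronological) == 0)
    stop("fit_bias_correction: degenerate fit, all chronological ages identical")
  co <- stats::coef(stats::lm(predicted ~ chronological))
  structure(list(alpha = unname(co[2L]), beta = unname(co[1L])),
            class = "bias_correction")
}

#' @rdname fit_bias_correction
#' @param model a fitted `bias_correction`.
#' @return `apply_bias_correction`: corrected predicted ages in years.
#' @export
apply_bias_correction <- function(predicted, chronological, model) {
  stopifnot(inherits(model, "bias_correction"))
  predicted + (chronological - (chronological * model$alpha + model$beta))
}

#' Brain age gap
#'
#' `BAG = corrected predicted age - chronological age`; positive values
#' indicate accelerated brain aging.
#'
#' @param corrected corrected predicted ages in years.
#' @param chronological chronological ages in years.
#' @return BAG in years.
#' @export
compute_bag <- function(corrected, chronological) {
  if (length(corrected) != length(chronological))
    stop("compute_bag: misaligned vectors")
  corrected - chronological
}

#' Full brain-age stage: CV training, per-fold bias correction, BAG
#'
#' Runs [train_regressor()], then, within each CV iteration, fits the bias
#' correction on that iteration's validation predictions and applies it to
#' the iteration's test predictions, so the correction is never fitted on
#' the data it corrects.
#'
#' @inheritParams train_regressor
#' @return object of class `brain_age_result`: `result` data.frame
#'   (`age`, `predicted`, `corrected`, `bag`), per-fold table
#'   (`mae_raw`, `mae_corrected`, `alpha`, `beta`), and pooled MAEs.
#' @export
brain_age_pipeline <- function(features, ages, config = regressor_config(),
                               folds) {
  fit <- train_regressor(features, ages, config, folds)
  corrected <- rep(NA_real_, length(ages))
  fold_tab <- data.frame(fold = 0:(folds$k - 1L), mae_raw = NA_real_,
                         mae_corrected = NA_real_, alpha = NA_real_,
                         beta = NA_real_)
  for (f in 0:(folds$k - 1L)) {
    pf <- fit$per_fold[[f + 1L]]
    bc <- fit_bias_correction(pf$val_predicted, ages[pf$roles$validation])
    test <- pf$roles$test
    corrected[test] <- apply_bias_correction(fit$predicted[test], ages[test], bc)
    fold_tab$mae_raw[f + 1L] <- mean(abs(fit$predicted[test] - ages[test]))
    fold_tab$mae_corrected[f + 1L] <- mean(abs(corrected[test] - ages[test]))
    fold_tab$alpha[f + 1L] <- bc$alpha
    fold_tab$beta[f + 1L] <- bc$beta
  }
  bag <- compute_bag(corrected, ages)
  structure(list(
    result = data.frame(age = ages, predicted = fit$predicted,
                        corrected = corrected, bag = bag),
    per_fold = fold_tab,
    mae_raw = mean(abs(fit$predicted - ages)),
    mae_corrected = mean(abs(corrected - ages)),
    fit = fit), class = "brain_age_result")
}

#' @export
print.brain_age_result <- function(x, ...) {
  cat("Brain-age CV result:", nrow(x$result), "subjects,",
      nrow(x$per_fold), "folds\n")
  cat(sprintf("  pooled MAE raw:       %.3f years\n", x$mae_raw))
  cat(sprintf("  pooled MAE corrected: %.3f years\n", x$mae_corrected))
  cat(sprintf("  mean BAG: %.3f years (SD %.3f)\n",
              mean(x$result$bag), stats::sd(x$result$bag)))
  invisible(x)
}
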