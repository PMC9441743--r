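test_that("stratified folds partition subjects and balance sizes", {
  ages <- stats::runif(100, 21, 82)
  f <- make_stratified_folds(ages, k = 10, seed = 1)
  expect_equal(as.vector(table(f$fold)), rep(10L, 10))
  # identical ages: any partition valid, sizes differ by <= 1
  f2 <- make_stratified_folds(rep(50, 95), k = 10, seed = 1)
  expect_lte(diff(range(table(f2$fold))), 1)
  expect_error(make_stratified_folds(stats::runif(5), k = 10), "at least k")
})

test_that("age stratification keeps fold means within a year of the grand mean", {
  set.seed(42)
  ages <- stats::runif(2000, 21, 82)
  f <- make_stratified_folds(ages, k = 10, seed = 3)
  fold_means <- tapply(ages, f$fold, mean)
  expect_lt(max(abs(fold_means - mean(ages))), 1)
})

test_that("fold roles are disjoint with a ~15% validation split", {
  ages <- stats::runif(600, 21, 82)
  f <- make_stratified_folds(ages, k = 10, seed = 2)
  for (tf in c(0L, 5L, 9L)) {
    r <- fold_roles(f, ages, tf)
    expect_length(intersect(r$train, r$test), 0)
    expect_length(intersect(r$validation, r$test), 0)
    expect_length(intersect(r$train, r$validation), 0)
    expect_setequal(c(r$train, r$validation, r$test), seq_along(ages))
    expect_equal(length(r$validation) / (length(r$train) + length(r$validation)),
                 0.15, tolerance = 0.02)
  }
})

test_that("bias correction recovers exact and noisy linear distortions", {
  age <- stats::runif(500, 21, 82)
  # identity predictions
  bc <- fit_bias_correction(age, age)
  expect_equal(bc$alpha, 1, tolerance = 1e-10)
  expect_equal(bc$beta, 0, tolerance = 1e-8)
  expect_equal(apply_bias_correction(age, age, bc), age, tolerance = 1e-8)
  # exact affine distortion: alpha/beta recovered, correction cancels it
  pred <- 0.5 * age + 25
  bc2 <- fit_bias_correction(pred, age)
  expect_equal(bc2$alpha, 0.5, tolerance = 1e-10)
  expect_equal(bc2$beta, 25, tolerance = 1e-8)
  expect_equal(apply_bias_correction(pred, age, bc2), age, tolerance = 1e-8)
  # noisy regression-to-the-mean: alpha_hat within its own 95% CI of 0.6
  set.seed(8)
  age2 <- stats::runif(1000, 21, 82)
  pred2 <- 0.6 * age2 + 20 + stats::rnorm(1000, 0, 4)
  fit <- stats::lm(pred2 ~ age2)
  ci <- stats::confint(fit, "age2", level = 0.95)
  expect_gte(0.6, ci[1]); expect_lte(0.6, ci[2])
  expect_error(fit_bias_correction(c(50, 55), c(40, 40)), "degenerate")
})

test_that("correction drives the residual age trend to zero in-sample", {
  set.seed(13)
  age <- stats::runif(2000, 21, 82)
  pred <- 0.7 * age + 15 + stats::rnorm(2000, 0, 5)
  bc <- fit_bias_correction(pred, age)
  corrected <- apply_bias_correction(pred, age, bc)
  bag <- compute_bag(corrected, age)
  slope <- stats::coef(stats::lm(bag ~ age))[2]
  expect_lt(abs(slope), 1e-6)
  # zero-mean-residual property of least squares
  expect_lt(abs(mean(bag)), 0.1)
})

test_that("BAG is the corrected-minus-chronological difference", {
  expect_equal(compute_bag(c(50, 60), c(50, 60)), c(0, 0))
  expect_equal(compute_bag(54, 50), 4)
  # a +4-year gap lands in the accelerated ("high") category
  expect_equal(discretize_value(compute_bag(54, 50), "BAG"), 2L)
})

test_that("corrected MAE does not exceed raw MAE under attenuation bias", {
  set.seed(77)
  age <- stats::runif(1200, 21, 82)
  pred <- 0.6 * age + 20 + stats::rnorm(1200, 0, 3)   # alpha_true < 1
  val <- sample(1200, 400)
  bc <- fit_bias_correction(pred[val], age[val])
  test <- setdiff(seq_len(1200), val)
  corrected <- apply_bias_correction(pred[test], age[test], bc)
  expect_lte(mean(abs(corrected - age[test])),
             mean(abs(pred[test] - age[test])))
})

test_that("the regressor reaches the learnable limit on noise-free features", {
  set.seed(31)
  co <- data.frame(subject_id = 1:300, age = stats::runif(300, 21, 82))
  f0 <- generate_morphometrics(co, noise_sd = rep(0, 223), seed = 3)
  folds <- make_stratified_folds(co$age, k = 5, seed = 4)
  cfg <- regressor_config(hidden = c(256L, 128L), max_epochs = 300, seed = 1)
  fit <- train_regressor(f0, co$age, cfg, folds)
  expect_true(all(is.finite(fit$predicted)))
  expect_lt(mean(abs(fit$predicted - co$age)), 1)
})

test_that("constant features collapse to the best constant predictor", {
  set.seed(32)
  co <- data.frame(subject_id = 1:200, age = stats::runif(200, 21, 82))
  fc <- generate_morphometrics(co, slopes = rep(0, 223),
                               noise_sd = rep(0, 223), seed = 5)
  folds <- make_stratified_folds(co$age, k = 5, seed = 6)
  cfg <- regressor_config(hidden = 256L, max_epochs = 100, seed = 2)
  fit <- train_regressor(fc, co$age, cfg, folds)
  mad0 <- mean(abs(co$age - mean(co$age)))
  expect_equal(mean(abs(fit$predicted - co$age)), mad0, tolerance = 0.05)
})

test_that("the pipeline is invariant to subject order", {
  set.seed(33)
  co <- data.frame(subject_id = 1:150, age = stats::runif(150, 21, 82))
  ft <- generate_morphometrics(co, seed = 7)
  cfg <- regressor_config(hidden = 256L, max_epochs = 60, seed = 3)
  run <- function(ord) {
    folds <- make_stratified_folds(co$age[ord], k = 5, seed = 8)
    fit <- train_regressor(ft[ord, ], co$age[ord], cfg, folds)
    mean(abs(fit$predicted - co$age[ord]))
  }
  perm <- sample(150)
  expect_equal(run(seq_len(150)), run(perm), tolerance = 1e-6)
})

test_that("architecture selection is deterministic and tracks its own report", {
  set.seed(34)
  co <- data.frame(subject_id = 1:150, age = stats::runif(150, 21, 82))
  ft <- generate_morphometrics(co, noise_sd = rep(1, 223), seed = 9)
  folds <- make_stratified_folds(co$age, k = 5, seed = 10)
  one <- select_architecture(ft, co$age, candidates = list(256L), folds = folds,
                             max_epochs = 40, seed = 4)
  expect_identical(one$hidden, 256L)
  cands <- list(256L, c(256L, 128L))
  pick1 <- select_architecture(ft, co$age, candidates = cands, folds = folds,
                               max_epochs = 40, seed = 4)
  pick2 <- select_architecture(ft, co$age, candidates = cands, folds = folds,
                               max_epochs = 40, seed = 4)
  expect_identical(pick1$hidden, pick2$hidden)
  rep1 <- attr(pick1, "report")
  expect_equal(nrow(rep1), 2L)
  best <- order(rep1$mae, rep1$n_parameters)[1]
  expect_identical(pick1$hidden, cands[[best]])
  expect_error(regressor_config(hidden = c(512L, 64L)), "must be one of")
})

test_that("bias correction is fitted on validation data, never on test data", {
  set.seed(35)
  co <- data.frame(subject_id = 1:200, age = stats::runif(200, 21, 82))
  ft <- generate_morphometrics(co, noise_sd = rep(2, 223), seed = 11)
  folds <- make_stratified_folds(co$age, k = 4, seed = 12)
  cfg <- regressor_config(hidden = 256L, max_epochs = 40, seed = 5)
  ba <- brain_age_pipeline(ft, co$age, cfg, folds)
  for (pf in ba$fit$per_fold) {
    expect_length(intersect(pf$roles$validation, pf$roles$test), 0)
    # the fold's alpha/beta reproduce from the validation predictions alone
    bc <- fit_bias_correction(pf$val_predicted, co$age[pf$roles$validation])
    f <- folds$fold[pf$roles$test[1]]
    expect_equal(ba$per_fold$alpha[f + 1L], bc$alpha)
    expect_equal(ba$per_fold$beta[f + 1L], bc$beta)
  }
  expect_equal(ba$result$bag, ba$result$corrected - ba$result$age)
})
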