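#' Synthetic morphometric feature table
#'
#' Generates the 223-column feature table standing in for the volumes,
#' surface areas and cortical thicknesses a surface-reconstruction pipeline
#' would extract from T1-weighted MRI. Each feature is an affine function of
#' a subject-level aging signal plus independent Gaussian noise:
#' `feature_j = intercept_j + slope_j * a_i + N(0, noise_sd_j)`,
#' where `a_i` is the chronological age by default, or a caller-supplied
#' "effective brain age" (chronological age plus a true brain-age offset)
#' when the features should carry an accelerated-aging signal.
#'
#' The defaults are deterministic vectors (no RNG draw): slopes spread over
#' roughly [-1.5, 1.5] per year with mixed signs, intercepts over
#' [60, 140], and a common noise SD of 5. They are chosen so that age is
#' recoverable from the joint feature set but no single feature is a clean
#' proxy, qualitatively like real morphometry; no attempt is made to mimic
#' real feature covariance.
#'
#' @param cohort a cohort `data.frame` with an `age` column (nonempty).
#' @param slopes numeric vector of per-feature slopes (length `n_features`).
#' @param noise_sd per-feature noise SDs, all `>= 0`.
#' @param intercepts per-feature intercepts.
#' @param seed integer RNG seed.
#' @param brain_age optional numeric vector overriding `cohort$age` as the
#'   aging signal (same length as the cohort).
#' @param n_features number of features (223, matching the morphometric
#'   feature count the pipeline emulates).
#' @return `data.frame`: `subject_id` plus `feat_001 ... feat_223`.
#' @export
generate_morphometrics <- function(cohort, slopes = NULL, noise_sd = NULL,
                                   intercepts = NULL, seed = 20220822L,
                                   brain_age = NULL, n_features = 223L) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("generate_morphometrics: 'cohort' must be a nonempty data.frame")
  if (is.null(brain_age)) {
    if (is.null(cohort$age))
      stop("generate_morphometrics: cohort lacks an 'age' column")
    brain_age <- cohort$age
  }
  n <- nrow(cohort)
  if (length(brain_age) != n)
    stop("generate_morphometrics: 'brain_age' length must match the cohort")
  j <- seq_len(n_features)
  if (is.null(slopes)) slopes <- 1.5 * sin(j / 7)
  if (is.null(noise_sd)) noise_sd <- rep(5, n_features)
  if (is.null(intercepts)) intercepts <- 100 + 40 * cos(j / 5)
  if (length(slopes) != n_features || length(noise_sd) != n_features ||
      length(intercepts) != n_features)
    stop("generate_morphometrics: slopes/noise_sd/intercepts must have ",
         n_features, " entries")
  if (any(noise_sd < 0))
    stop("generate_morphometrics: 'noise_sd' entries must be >= 0")
  set.seed(seed)
  feats <- matrix(stats::rnorm(n * n_features), n, n_features)
  feats <- sweep(feats, 2L, noise_sd, `*`)
  feats <- feats + outer(brain_age, slopes) +
    matrix(intercepts, n, n_features, byrow = TRUE)
  colnames(feats) <- sprintf("feat_%03d", j)
  cbind(data.frame(subject_id = cohort$subject_id %||% seq_len(n)),
        as.data.frame(feats))
}
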