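#' Age-stratified cross-validation folds
#'
#' Subjects are binned into age deciles; within each bin the (age-sorted)
#' members are shuffled and dealt round-robin across the `k` folds, with the
#' dealing offset carried from bin to bin so fold sizes differ by at most
#' one. This keeps the fold-wise age distributions closely matched. Because
#' bin members are ordered by age before the seeded shuffle, the partition
#' is invariant to the order subjects arrive in (up to exact age ties).
#'
#' @param ages numeric vector of chronological ages in years.
#' @param k number of folds (`>= 2`, `<= length(ages)`).
#' @param validation_fraction fraction of each training portion later held
#'   out for early stopping (see [fold_roles()]); default 0.15.
#' @param seed integer RNG seed.
#' @return an object of class `fold_assignment`: per-subject fold index in
#'   `{0, ..., k-1}` plus the parameters.
#' @export
make_stratified_folds <- function(ages, k = 10L, validation_fraction = 0.15,
                                  seed = 1L) {
  n <- length(ages)
  if (k < 2) stop("make_stratified_folds: 'k' must be >= 2")
  if (n < k) stop("make_stratified_folds: need at least k subjects (n = ",
                  n, ", k = ", k, ")")
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop("make_stratified_folds: 'validation_fraction' must be in [0, 1)")
  set.seed(seed)
  bins <- age_decile_bins(ages)
  fold <- integer(n)
  offset <- 0L
  for (b in sort(unique(bins))) {
    idx <- which(bins == b)
    idx <- idx[order(ages[idx])]              # order-invariance anchor
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- (offset + seq_along(idx) - 1L) %% k
    offset <- (offset + length(idx)) %% k
  }
  structure(list(fold = fold, k = as.integer(k),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

age_decile_bins <- function(ages, n_bins = 10L) {
  qs <- stats::quantile(ages, probs = seq(0, 1, length.out = n_bins + 1L),
                        type = 7)
  qs <- unique(qs)                            # collapse ties (constant ages)
  if (length(qs) < 2L) return(rep(1L, length(ages)))
  as.integer(cut(ages, breaks = qs, include.lowest = TRUE, labels = FALSE))
}

#' Train / validation / test roles for one CV iteration
#'
#' The test set is fold `test_fold`; from the remaining subjects an
#' age-stratified `validation_fraction` is split off for early stopping and
#' bias-correction fitting, and the rest trains the model. The validation
#' draw is deterministic given the assignment and the test fold.
#'
#' @param folds a [make_stratified_folds()] assignment.
#' @param ages the age vector the folds were built from.
#' @param test_fold fold index in `{0, ..., k-1}`.
#' @return list with integer index vectors `train`, `validation`, `test`.
#' @export
fold_roles <- function(folds, ages, test_fold) {
  stopifnot(inherits(folds, "fold_assignment"))
  if (!(test_fold %in% 0:(folds$k - 1L)))
    stop("fold_roles: 'test_fold' out of range")
  test <- which(folds$fold == test_fold)
  pool <- which(folds$fold != test_fold)
  set.seed((folds$seed * 131L + as.integer(test_fold) + 7L) %% 2147483587L)
  bins <- age_decile_bins(ages[pool])
  val <- integer()
  for (b in sort(unique(bins))) {
    idx <- pool[bins == b]
    idx <- idx[order(ages[idx])]
    take <- round(folds$validation_fraction * length(idx))
    if (take > 0L) val <- c(val, idx[sample.int(length(idx), take)])
  }
  list(train = setdiff(pool, val), validation = sort(val), test = test)
}
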