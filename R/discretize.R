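#' Clinical discretization scheme
#'
#' Fixed three-level categorization of the continuous model variables, using
#' common clinical cut-offs: BMI `<25 / 25-30 / >30` kg/m^2, systolic BP
#' `<120 / 120-140 / >140` mmHg, waist-to-hip ratio with sex-specific edges
#' (males `<0.95 / 0.95-1 / >1`, females `<0.8 / 0.8-0.85 / >0.85`), age
#' `<35 / 35-65 / >65` years, and brain age gap `<-3 / -3 to 3 / >3` years
#' (delayed / normal / accelerated brain aging). Sex, smoking and drinking
#' pass through with their native codes.
#'
#' Boundary convention: the outer bins are open (`< e1`, `> e2`), so values
#' exactly at an edge fall in the closed middle ("normal") bin.
#'
#' @return an object of class `discretization_scheme`.
#' @export
default_scheme <- function() {
  structure(list(
    variables = list(
      BMI = list(edges = c(25, 30)),
      BP  = list(edges = c(120, 140)),
      WHR = list(sex_specific = TRUE,
                 edges_male = c(0.95, 1), edges_female = c(0.8, 0.85)),
      age = list(edges = c(35, 65)),
      BAG = list(edges = c(-3, 3))
    ),
    labels = c("low", "normal", "high"),
    passthrough = list(sex = 0:1, smoking = 0:2, drinking = 0:2)
  ), class = "discretization_scheme")
}

scheme_needs_sex <- function(scheme, variable) {
  v <- scheme$variables[[variable]]
  !is.null(v) && isTRUE(v$sex_specific)
}

#' Discretize a continuous value into low / normal / high
#'
#' Category codes are ordered `0 = low, 1 = normal, 2 = high` for every
#' variable. Values below the first edge map to 0, values in the closed
#' interval `[e1, e2]` to 1, values above the second edge to 2.
#'
#' @param value numeric vector.
#' @param variable variable name known to the scheme (e.g. `"BMI"`).
#' @param sex per-value sex codes (0 = male, 1 = female); required for
#'   sex-specific variables (WHR), ignored otherwise.
#' @param scheme a [default_scheme()]-style scheme.
#' @return integer codes in `{0, 1, 2}`.
#' @export
discretize_value <- function(value, variable, sex = NULL,
                             scheme = default_scheme()) {
  v <- scheme$variables[[variable]]
  if (is.null(v))
    stop("discretize_value: variable '", variable, "' unknown to the scheme")
  if (isTRUE(v$sex_specific)) {
    if (is.null(sex))
      stop("discretize_value: '", variable, "' uses sex-specific thresholds; ",
           "'sex' is required")
    sex <- rep_len(sex, length(value))
    if (!all(sex %in% 0:1))
      stop("discretize_value: 'sex' codes must be 0 (male) or 1 (female)")
    e1 <- ifelse(sex == 0, v$edges_male[1], v$edges_female[1])
    e2 <- ifelse(sex == 0, v$edges_male[2], v$edges_female[2])
  } else {
    e1 <- v$edges[1]; e2 <- v$edges[2]
  }
  if (any(!is.finite(value)))
    stop("discretize_value: non-finite values in '", variable, "'")
  as.integer((value >= e1) + (value > e2))
}

#' Discretize a cohort into the network's categorical variables
#'
#' Applies [discretize_value()] element-wise to every continuous model
#' variable and validates the passthrough codes of the native categorical
#' ones. No rows are dropped. A per-variable category frequency table is
#' attached as attribute `"frequencies"`.
#'
#' @param cohort cohort `data.frame`; must contain all scheme variables
#'   present in `variables` (plus passthrough columns).
#' @param scheme a [default_scheme()]-style scheme.
#' @param variables which columns to emit (default: every scheme variable
#'   found in the cohort, passthrough included).
#' @return `data.frame` of integer category codes, one row per subject.
#' @export
discretize_cohort <- function(cohort, scheme = default_scheme(),
                              variables = NULL) {
  stopifnot(is.data.frame(cohort))
  all_vars <- c(names(scheme$variables), names(scheme$passthrough))
  if (is.null(variables)) variables <- intersect(all_vars, names(cohort))
  missing <- setdiff(variables, names(cohort))
  if (length(missing))
    stop("discretize_cohort: missing column(s): ",
         paste(missing, collapse = ", "))
  out <- data.frame(row.names = seq_len(nrow(cohort)))
  for (v in variables) {
    if (v %in% names(scheme$passthrough)) {
      codes <- cohort[[v]]
      ok <- codes %in% scheme$passthrough[[v]]
      if (!all(ok))
        stop("discretize_cohort: invalid codes in passthrough column '", v, "'")
      out[[v]] <- as.integer(codes)
    } else {
      sex <- if (scheme_needs_sex(scheme, v)) cohort$sex else NULL
      out[[v]] <- discretize_value(cohort[[v]], v, sex = sex, scheme = scheme)
    }
  }
  attr(out, "frequencies") <- lapply(out, function(x) table(code = x))
  out
}

#' Write / read a discretization scheme as YAML
#' @param scheme a `discretization_scheme`.
#' @param path file path.
#' @export
write_scheme <- function(scheme, path) {
  yaml::write_yaml(unclass(scheme), path)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$passthrough <- lapply(raw$passthrough, as.integer)
  structure(raw, class = "discretization_scheme")
}
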