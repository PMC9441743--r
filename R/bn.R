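#' Fit conditional probability tables on a DAG
#'
#' Bayesian (Dirichlet) parameter estimation with a uniform prior of
#' `pseudo_count` per cell: each CPD row is the posterior mean
#' `(count + pseudo_count) / (row_total + pseudo_count * cardinality)`.
#' Parent configurations never observed get the uniform prior row (when
#' `pseudo_count > 0`; with a zero pseudo-count they raise an error).
#'
#' @param dag a [dag_structure()].
#' @param data discretized data.frame covering all DAG nodes.
#' @param pseudo_count nonnegative Dirichlet prior count per cell
#'   (default 1).
#' @param states optional named list fixing each node's state set (useful
#'   when fitting on a subset whose folds might miss a state); defaults to
#'   the sorted unique values observed in `data`.
#' @return object of class `bn_model`: the DAG plus one CPD per node. CPD
#'   rows are parent-state combinations (first parent varying fastest),
#'   columns are target states.
#' @export
fit_cpds <- function(dag, data, pseudo_count = 1, states = NULL) {
  stopifnot(inherits(dag, "dag_structure"))
  missing <- setdiff(dag$nodes, names(data))
  if (length(missing))
    stop("fit_cpds: data lacks column(s): ", paste(missing, collapse = ", "))
  if (pseudo_count < 0) stop("fit_cpds: 'pseudo_count' must be >= 0")
  if (is.null(states))
    states <- lapply(data[dag$nodes], function(x) as.character(sort(unique(x))))
  else states <- lapply(states[dag$nodes], as.character)
  nodes <- list()
  for (nm in dag$nodes) {
    parents <- dag_parents(dag, nm)
    child_f <- factor(as.character(data[[nm]]), levels = states[[nm]])
    if (anyNA(child_f)) stop("fit_cpds: value outside declared states in '",
                             nm, "'")
    if (length(parents)) {
      pf <- lapply(parents, function(p)
        factor(as.character(data[[p]]), levels = states[[p]]))
      cfg <- interaction(pf, lex.order = FALSE)  # first parent fastest
      counts <- table(cfg, child_f)
    } else {
      counts <- matrix(table(child_f), nrow = 1L)
    }
    counts <- matrix(as.numeric(counts), nrow = nrow(counts))
    totals <- rowSums(counts)
    card <- length(states[[nm]])
    if (pseudo_count == 0 && any(totals == 0))
      stop("fit_cpds: node '", nm, "' has unobserved parent configuration(s) ",
           "and pseudo_count = 0 leaves the CPD row undefined")
    cpt <- (counts + pseudo_count) / (totals + pseudo_count * card)
    colnames(cpt) <- states[[nm]]
    nodes[[nm]] <- list(states = states[[nm]], parents = parents, cpt = cpt)
  }
  structure(list(dag = dag, nodes = nodes, order = dag$order),
            class = "bn_model")
}

bn_cards <- function(model) {
  vapply(model$nodes, function(nd) length(nd$states), integer(1))
}

# --- discrete factors -------------------------------------------------------

# factor over 'vars' (cards from the model); values stored as an array with
# one dimension per var, in 'vars' order. Zero-var factors are scalars.
bn_factor <- function(vars, values, cards) {
  if (length(vars)) values <- array(values, dim = unname(cards[vars]))
  list(vars = vars, values = values)
}

# CPD of a node as a factor over c(parents, node); CPD rows vary the first
# parent fastest, matching array dimension order.
cpd_factor <- function(model, node) {
  nd <- model$nodes[[node]]
  cards <- bn_cards(model)
  bn_factor(c(nd$parents, node), as.vector(nd$cpt), cards)
}

factor_reduce <- function(f, var, state_idx, cards) {
  if (!(var %in% f$vars)) return(f)
  pos <- match(var, f$vars)
  others <- f$vars[-pos]
  a <- aperm(array(f$values, dim = unname(cards[f$vars])),
             c(pos, seq_along(f$vars)[-pos]))
  a <- array(a, dim = c(cards[[var]], prod(cards[others], 1)))
  bn_factor(others, a[state_idx, ], cards)
}

factor_marginalize <- function(f, var, cards) {
  if (!(var %in% f$vars)) return(f)
  pos <- match(var, f$vars)
  others <- f$vars[-pos]
  a <- aperm(array(f$values, dim = unname(cards[f$vars])),
             c(pos, seq_along(f$vars)[-pos]))
  a <- array(a, dim = c(cards[[var]], prod(cards[others], 1)))
  bn_factor(others, colSums(a), cards)
}

factor_product <- function(f1, f2, cards) {
  if (!length(f1$vars)) return(bn_factor(f2$vars, f2$values * as.numeric(f1$values), cards))
  if (!length(f2$vars)) return(bn_factor(f1$vars, f1$values * as.numeric(f2$values), cards))
  vars <- union(f1$vars, f2$vars)
  expand <- function(f) {
    extra <- setdiff(vars, f$vars)
    a <- array(f$values, dim = unname(cards[c(f$vars, extra)]))
    aperm(a, match(vars, c(f$vars, extra)))
  }
  bn_factor(vars, expand(f1) * expand(f2), cards)
}

# --- exact inference --------------------------------------------------------

#' Exact conditional query by variable elimination
#'
#' Computes `P(target | evidence)` on the fitted network. Evidence may be
#' any assignment over other nodes (including several at once, e.g.
#' sex-conditioned risk-factor queries). Hidden variables are eliminated in
#' a greedy min-width order; the result is exact regardless of the order.
#'
#' @param model a [fit_cpds()] model.
#' @param target node name.
#' @param evidence named list/vector of observed states (characters or the
#'   original codes), e.g. `list(BMI = 2, sex = 0)`.
#' @return object of class `distribution_result` with a probability per
#'   target state, `mode = "observational"`.
#' @export
query_conditional <- function(model, target, evidence = list()) {
  stopifnot(inherits(model, "bn_model"))
  if (!(target %in% names(model$nodes)))
    stop("query_conditional: unknown target '", target, "'")
  evidence <- as.list(evidence)
  if (target %in% names(evidence))
    stop("query_conditional: target cannot appear in the evidence")
  cards <- bn_cards(model)
  ev_idx <- list()
  for (v in names(evidence)) {
    if (!(v %in% names(model$nodes)))
      stop("query_conditional: unknown evidence node '", v, "'")
    idx <- match(as.character(evidence[[v]]), model$nodes[[v]]$states)
    if (is.na(idx))
      stop("query_conditional: invalid state '", evidence[[v]],
           "' for node '", v, "'")
    ev_idx[[v]] <- idx
  }
  factors <- lapply(names(model$nodes), function(nm) cpd_factor(model, nm))
  for (v in names(ev_idx))
    factors <- lapply(factors, factor_reduce, var = v,
                      state_idx = ev_idx[[v]], cards = cards)
  hidden <- setdiff(names(model$nodes), c(target, names(ev_idx)))
  while (length(hidden)) {
    width <- vapply(hidden, function(v) {
      involved <- vapply(factors, function(f) v %in% f$vars, logical(1))
      prod(cards[Reduce(union, lapply(factors[involved], `[[`, "vars"))])
    }, numeric(1))
    v <- hidden[which.min(width)]
    involved <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod_f <- Reduce(function(a, b) factor_product(a, b, cards),
                     factors[involved])
    factors <- c(factors[!involved],
                 list(factor_marginalize(prod_f, v, cards)))
    hidden <- setdiff(hidden, v)
  }
  res <- Reduce(function(a, b) factor_product(a, b, cards), factors)
  probs <- as.numeric(res$values)
  total <- sum(probs)
  if (total <= 0)
    stop("query_conditional: the evidence has probability zero under the model")
  distribution_result(target, stats::setNames(probs / total,
                                              model$nodes[[target]]$states),
                      mode = "observational", given = evidence)
}

distribution_result <- function(target, probs, mode, given = list()) {
  structure(list(target = target, probs = probs, mode = mode, given = given),
            class = "distribution_result")
}

#' @export
print.distribution_result <- function(x, ...) {
  giv <- if (length(x$given))
    paste0(" | ", paste(names(x$given), unlist(x$given),
                        sep = if (x$mode == "interventional") " := " else " = ",
                        collapse = ", "))
  else ""
  cat(sprintf("%s P(%s%s):\n", x$mode, x$target, giv))
  print(round(x$probs, 4))
  invisible(x)
}

#' Most probable state of a node given evidence
#'
#' Argmax of [query_conditional()]; ties break toward the lower state code.
#'
#' @inheritParams query_conditional
#' @return list with `state` and the full `probs` vector.
#' @export
predict_node <- function(model, target, evidence) {
  q <- query_conditional(model, target, evidence)
  list(state = names(q$probs)[which.max(q$probs)], probs = q$probs)
}

#' Per-subject node posteriors given all other variables
#'
#' Vectorized computation of `P(node | all other nodes)` for every row of
#' `data`, via the node's Markov blanket (its CPD times its children's
#' CPDs), which equals the full conditional exactly.
#'
#' @param model a [fit_cpds()] model.
#' @param data discretized data.frame covering all nodes.
#' @param node target node.
#' @return numeric matrix, rows = subjects, columns = node states.
#' @export
node_posteriors <- function(model, data, node) {
  nd <- model$nodes[[node]]
  if (is.null(nd)) stop("node_posteriors: unknown node '", node, "'")
  n <- nrow(data)
  codes <- lapply(names(model$nodes), function(v) {
    idx <- match(as.character(data[[v]]), model$nodes[[v]]$states)
    if (anyNA(idx)) stop("node_posteriors: value outside states in '", v, "'")
    idx
  })
  names(codes) <- names(model$nodes)
  card <- length(nd$states)
  row_index <- function(parents, override_node = NULL, override_val = NULL) {
    idx <- rep(1L, n); mult <- 1L
    for (p in parents) {
      ci <- if (identical(p, override_node)) rep(override_val, n) else codes[[p]]
      idx <- idx + (ci - 1L) * mult
      mult <- mult * length(model$nodes[[p]]$states)
    }
    idx
  }
  children <- names(model$nodes)[vapply(model$nodes,
                                        function(x) node %in% x$parents,
                                        logical(1))]
  post <- matrix(0, n, card, dimnames = list(NULL, nd$states))
  own_rows <- row_index(nd$parents)
  for (s in seq_len(card)) {
    p <- nd$cpt[own_rows, s]
    for (ch in children) {
      chd <- model$nodes[[ch]]
      rows <- row_index(chd$parents, override_node = node, override_val = s)
      p <- p * chd$cpt[cbind(rows, codes[[ch]])]
    }
    post[, s] <- p
  }
  tot <- rowSums(post)
  if (any(tot <= 0))
    stop("node_posteriors: zero-probability configuration encountered")
  post / tot
}

# macro one-vs-rest multiclass AUC; classes absent from the test data (or
# degenerate one-class splits) are skipped with a warning.
macro_ovr_auc <- function(y, post) {
  states <- colnames(post)
  aucs <- c()
  skipped <- character()
  for (s in states) {
    pos <- as.character(y) == s
    if (!any(pos) || all(pos)) { skipped <- c(skipped, s); next }
    r <- pROC::roc(response = pos, predictor = post[, s],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    aucs <- c(aucs, as.numeric(pROC::auc(r)))
  }
  if (length(skipped))
    warning("macro AUC: class(es) ", paste(skipped, collapse = ", "),
            " absent from the test data; skipped in the macro average")
  mean(aucs)
}

#' Repeated cross-validated node-prediction AUC
#'
#' Validates a network structure the way the study does: in each of
#' `repeats` repetitions, a fresh `k`-fold split is drawn; per fold the
#' CPDs are refitted on the training folds and every node is predicted for
#' the held-out subjects from all other variables. The AUC per node and
#' repetition is the macro one-vs-rest AUC pooled over that repetition's
#' test folds; means and SDs are reported across repetitions, plus the
#' overall average over nodes.
#'
#' @param dag a [dag_structure()].
#' @param data discretized data.frame covering all nodes.
#' @param k folds (default 10).
#' @param repeats repetitions (default 10).
#' @param seed integer seed.
#' @param pseudo_count Dirichlet prior per cell for the fold fits.
#' @return object of class `bn_cv_report`: `report` data.frame
#'   (`node`, `auc_mean`, `auc_sd`) and the overall `average`.
#' @export
crossvalidated_auc <- function(dag, data, k = 10L, repeats = 10L, seed = 1L,
                               pseudo_count = 1) {
  stopifnot(inherits(dag, "dag_structure"))
  n <- nrow(data)
  if (n < k) stop("crossvalidated_auc: need at least k rows")
  states <- lapply(data[dag$nodes], function(x) as.character(sort(unique(x))))
  degenerate <- names(states)[vapply(states, length, integer(1)) < 2L]
  if (length(degenerate))
    warning("crossvalidated_auc: node(s) with a single observed state ",
            "reported as NA: ", paste(degenerate, collapse = ", "))
  scored <- setdiff(dag$nodes, degenerate)
  per_rep <- matrix(NA_real_, repeats, length(dag$nodes),
                    dimnames = list(NULL, dag$nodes))
  for (r in seq_len(repeats)) {
    set.seed((seed + 7919L * (r - 1L)) %% 2147483587L)
    fold <- sample(rep_len(0:(k - 1L), n))
    post <- lapply(dag$nodes, function(nm)
      matrix(NA_real_, n, length(states[[nm]]),
             dimnames = list(NULL, states[[nm]])))
    names(post) <- dag$nodes
    for (f in 0:(k - 1L)) {
      train <- data[fold != f, , drop = FALSE]
      test <- data[fold == f, , drop = FALSE]
      model <- fit_cpds(dag, train, pseudo_count = pseudo_count,
                        states = states)
      for (nm in scored)
        post[[nm]][fold == f, ] <- node_posteriors(model, test, nm)
    }
    for (nm in scored)
      per_rep[r, nm] <- macro_ovr_auc(data[[nm]], post[[nm]])
  }
  report <- data.frame(node = dag$nodes,
                       auc_mean = colMeans(per_rep),
                       auc_sd = apply(per_rep, 2L, stats::sd),
                       row.names = NULL)
  structure(list(report = report,
                 average = mean(report$auc_mean, na.rm = TRUE),
                 k = k, repeats = repeats),
            class = "bn_cv_report")
}

#' @export
print.bn_cv_report <- function(x, ...) {
  cat(sprintf("Node-prediction AUC (%d x %d-fold CV):\n", x$repeats, x$k))
  print(transform(x$report, auc_mean = round(auc_mean, 3),
                  auc_sd = round(auc_sd, 4)), row.names = FALSE)
  cat(sprintf("  average over nodes: %.3f\n", x$average))
  invisible(x)
}

# --- serialization ----------------------------------------------------------

#' Serialize / read a fitted network as JSON (round-trip safe)
#' @param model a [fit_cpds()] model.
#' @param path file path.
#' @export
write_bn_json <- function(model, path) {
  ser <- list(
    nodes = model$dag$nodes,
    edges = model$dag$edges,
    threshold = model$dag$threshold,
    cpds = lapply(model$nodes, function(nd)
      list(states = nd$states, parents = nd$parents,
           cpt = apply(nd$cpt, 1L, identity, simplify = FALSE))))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "list")
  invisible(path)
}

#' @rdname write_bn_json
#' @export
read_bn_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  edges <- as.data.frame(raw$edges)
  if (!nrow(edges)) edges <- data.frame(parent = character(),
                                        child = character(),
                                        weight = numeric())
  dag <- dag_structure(raw$nodes, edges,
                       threshold = raw$threshold %||% NA_real_)
  nodes <- lapply(raw$cpds, function(nd) {
    cpt <- do.call(rbind, nd$cpt)
    colnames(cpt) <- nd$states
    list(states = as.character(nd$states),
         parents = as.character(unlist(nd$parents)), cpt = cpt)
  })
  structure(list(dag = dag, nodes = nodes[dag$nodes], order = dag$order),
            class = "bn_model")
}
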