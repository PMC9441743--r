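#' Intervene on a node (do-operator by graph mutilation)
#'
#' `do(node = state)`: all incoming edges of the node are severed and its
#' CPD is replaced by a point mass on `state`; every other CPD is left
#' untouched. Repeated interventions on the same node are idempotent (the
#' last assignment wins). For a fully specified discrete model this graph
#' mutilation is equivalent to symbolic do-calculus for point
#' interventions.
#'
#' @param model a [fit_cpds()] model.
#' @param do_node node to intervene on.
#' @param do_state state to clamp it to.
#' @return a mutilated `bn_model`.
#' @export
intervene <- function(model, do_node, do_state) {
  stopifnot(inherits(model, "bn_model"))
  nd <- model$nodes[[do_node]]
  if (is.null(nd)) stop("intervene: unknown node '", do_node, "'")
  idx <- match(as.character(do_state), nd$states)
  if (is.na(idx)) stop("intervene: invalid state '", do_state,
                       "' for node '", do_node, "'")
  cpt <- matrix(0, 1L, length(nd$states), dimnames = list(NULL, nd$states))
  cpt[1L, idx] <- 1
  model$nodes[[do_node]] <- list(states = nd$states, parents = character(),
                                 cpt = cpt)
  keep <- model$dag$edges$child != do_node
  model$dag <- dag_structure(model$dag$nodes,
                             model$dag$edges[keep, , drop = FALSE],
                             threshold = model$dag$threshold)
  model$order <- model$dag$order
  model$interventions <- c(model$interventions[setdiff(names(model$interventions),
                                                       do_node)],
                           stats::setNames(list(as.character(do_state)), do_node))
  model
}

#' Interventional distribution of a target node
#'
#' `P(target | do(do_node = do_state))`: exact inference on the mutilated
#' network with empty evidence.
#'
#' @inheritParams intervene
#' @param target node whose distribution is evaluated.
#' @return a `distribution_result` flagged `"interventional"`.
#' @export
interventional_distribution <- function(model, target, do_node, do_state) {
  if (identical(target, do_node))
    stop("interventional_distribution: target cannot be the do-node")
  q <- query_conditional(intervene(model, do_node, do_state), target,
                         evidence = list())
  distribution_result(target, q$probs, mode = "interventional",
                      given = stats::setNames(list(as.character(do_state)),
                                              do_node))
}

#' Observational vs. interventional distributions per risk-factor state
#'
#' For every state `s` of `risk_factor`, pairs the observational
#' `P(target | risk_factor = s)` with the interventional
#' `P(target | do(risk_factor = s))`. For parentless risk factors the two
#' columns coincide; for confounded ones they differ.
#'
#' @param model a [fit_cpds()] model.
#' @param risk_factor conditioning / intervention node.
#' @param target read-out node (typically `"BAG"`).
#' @return object of class `ovi_table`: a data.frame with columns `state`,
#'   `mode`, and one probability column per target state.
#' @export
observe_vs_intervene_table <- function(model, risk_factor, target) {
  if (identical(risk_factor, target))
    stop("observe_vs_intervene_table: risk factor and target must differ")
  states <- model$nodes[[risk_factor]]$states
  if (is.null(states))
    stop("observe_vs_intervene_table: unknown node '", risk_factor, "'")
  rows <- list()
  for (s in states) {
    obs <- query_conditional(model, target,
                             stats::setNames(list(s), risk_factor))
    int <- interventional_distribution(model, target, risk_factor, s)
    rows[[length(rows) + 1L]] <- data.frame(state = s, mode = "observational",
                                            t(obs$probs), check.names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(state = s, mode = "interventional",
                                            t(int$probs), check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "risk_factor") <- risk_factor
  attr(out, "target") <- target
  class(out) <- c("ovi_table", "data.frame")
  out
}

#' @export
plot.ovi_table <- function(x, ...) {
  target <- attr(x, "target"); rf <- attr(x, "risk_factor")
  pcols <- setdiff(names(x), c("state", "mode"))
  states <- unique(x$state)
  cols <- grDevices::hcl.colors(length(states), "Dark 2")
  graphics::matplot(seq_along(pcols),
                    t(as.matrix(x[x$mode == "observational", pcols])),
                    type = "l", lty = 1, col = cols, ylim = c(0, 1),
                    xaxt = "n", xlab = paste(target, "category"),
                    ylab = "probability",
                    main = paste0("P(", target, " | ", rf,
                                  ") observe (solid) vs intervene (dashed)"),
                    ...)
  graphics::matlines(seq_along(pcols),
                     t(as.matrix(x[x$mode == "interventional", pcols])),
                     lty = 2, col = cols)
  graphics::axis(1, at = seq_along(pcols), labels = pcols)
  graphics::legend("topright", legend = paste(rf, "=", states),
                   col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Classify the association sign of a DAG edge
#'
#' Computes the expected child state code
#' `m(s) = sum_c code(c) * P(child = c | parent = s)` for each parent state
#' `s` in ascending code order, marginalizing over the child's other
#' parents. A monotone increasing profile is a positive association, a
#' monotone decreasing one negative, anything else (including V-shapes)
#' nonlinear; a constant profile is flagged as a zero effect.
#'
#' @param model a [fit_cpds()] model.
#' @param parent,child an edge present in the DAG.
#' @return object of class `edge_sign`: `label` in
#'   `{"positive", "negative", "nonlinear"}`, the profile `m`, and
#'   `zero_effect`.
#' @export
classify_edge_sign <- function(model, parent, child) {
  present <- any(model$dag$edges$parent == parent &
                 model$dag$edges$child == child)
  if (!present)
    stop("classify_edge_sign: edge ", parent, " -> ", child,
         " is not in the DAG")
  p_states <- model$nodes[[parent]]$states
  c_states <- model$nodes[[child]]$states
  codes <- suppressWarnings(as.numeric(c_states))
  if (anyNA(codes)) codes <- seq_along(c_states) - 1
  m <- vapply(p_states, function(s) {
    q <- query_conditional(model, child, stats::setNames(list(s), parent))
    sum(codes * q$probs)
  }, numeric(1))
  tol <- 1e-12
  d <- diff(m)
  zero <- all(abs(d) < tol)
  label <- if (zero) "nonlinear"
  else if (all(d >= -tol) && m[length(m)] > m[1L] + tol) "positive"
  else if (all(d <= tol) && m[length(m)] < m[1L] - tol) "negative"
  else "nonlinear"
  structure(list(parent = parent, child = child, label = label,
                 m = m, zero_effect = zero),
            class = "edge_sign")
}

#' @rdname classify_edge_sign
#' @return `classify_all_edges`: data.frame with one row per DAG edge
#'   (`parent`, `child`, `label`, `zero_effect`).
#' @export
classify_all_edges <- function(model) {
  e <- model$dag$edges
  out <- e[, c("parent", "child")]
  out$label <- NA_character_
  out$zero_effect <- NA
  for (i in seq_len(nrow(e))) {
    s <- classify_edge_sign(model, e$parent[i], e$child[i])
    out$label[i] <- s$label
    out$zero_effect[i] <- s$zero_effect
  }
  out
}
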