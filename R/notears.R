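#' Smooth acyclicity score of a weighted adjacency matrix
#'
#' `h(W) = trace(exp(W o W)) - d`, where `o` is the element-wise product:
#' zero exactly when the support of `W` is acyclic, strictly positive
#' otherwise. This is the continuous DAG constraint at the heart of the
#' NOTEARS formulation of structure learning.
#'
#' @param W square numeric matrix.
#' @return nonnegative scalar.
#' @export
acyclicity_h <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("acyclicity_h: 'W' must be square")
  E <- as.matrix(Matrix::expm(W * W))
  sum(diag(E)) - nrow(W)
}

#' Forbidden-edge constraints for structure discovery
#'
#' Encodes domain knowledge as hard constraints: the named variables in
#' `no_incoming` may not receive any edge (nothing can affect age or sex),
#' those in `no_outgoing` may not emit any edge (the brain age gap is a
#' read-out, not a cause), and each `forbidden_pairs` row bans one ordered
#' parent-to-child edge (by default the obesity/blood-pressure markers BMI,
#' WHR and BP cannot affect smoking or drinking behaviour).
#'
#' @param variables variable names, in data-column order.
#' @param no_incoming variables that may not have parents.
#' @param no_outgoing variables that may not have children.
#' @param forbidden_pairs 2-column matrix or data.frame of ordered
#'   `(parent, child)` pairs to ban.
#' @return object of class `constraint_set` with a logical `forbidden`
#'   matrix (`[i, j]` TRUE bans the edge `i -> j`).
#' @export
default_constraints <- function(variables = study_variables(),
                                no_incoming = c("age", "sex"),
                                no_outgoing = "BAG",
                                forbidden_pairs = rbind(
                                  expand.grid(parent = c("BMI", "WHR", "BP"),
                                              child = c("smoking", "drinking"),
                                              stringsAsFactors = FALSE))) {
  d <- length(variables)
  forbidden <- matrix(FALSE, d, d, dimnames = list(variables, variables))
  known <- function(v) {
    bad <- setdiff(v, variables)
    if (length(bad)) stop("default_constraints: unknown variable(s): ",
                          paste(bad, collapse = ", "))
    v
  }
  forbidden[, known(intersect(no_incoming, variables))] <- TRUE
  forbidden[known(intersect(no_outgoing, variables)), ] <- TRUE
  if (!is.null(forbidden_pairs) && nrow(forbidden_pairs)) {
    fp <- as.matrix(forbidden_pairs[, 1:2])
    keep <- fp[, 1] %in% variables & fp[, 2] %in% variables
    fp <- fp[keep, , drop = FALSE]
    forbidden[fp] <- TRUE
  }
  diag(forbidden) <- TRUE
  structure(list(variables = variables, forbidden = forbidden),
            class = "constraint_set")
}

#' @rdname default_constraints
#' @export
study_variables <- function() {
  c("sex", "age", "WHR", "BMI", "BP", "smoking", "drinking", "BAG")
}

#' Encode a cohort for continuous structure learning
#'
#' Sex stays `{0, 1}` and smoking/drinking stay ordinal `{0, 1, 2}`.
#' Continuous variables are rescaled so all columns live on comparable
#' numeric ranges. The default `"clinical"` scaling divides each variable
#' by a fixed, clinically meaningful constant -- the width of its "normal"
#' category in the discretization scheme (BMI/5 kg/m^2, BP/20 mmHg,
#' WHR/0.05, age/30 y, BAG/6 y). Unlike empirical per-column
#' standardization (available as `scaling = "unit_sd"`), fixed constants
#' preserve the variance ordering between a cause and its effects; with
#' every column forced to unit variance, reversed edge orientations tie
#' exactly in the least-squares score of a linear-Gaussian system, and the
#' discovery step degrades to near-chance orientation.
#'
#' @param cohort cohort data.frame containing the model variables.
#' @param scaling `"clinical"` (fixed constants) or `"unit_sd"` (z-score).
#' @param continuous names of continuous columns.
#' @param variables output column order.
#' @return numeric data.frame ready for [learn_weighted_adjacency()]
#'   (columns are centred by the learner itself).
#' @export
encode_for_structure_learning <- function(cohort,
                                          scaling = c("clinical", "unit_sd"),
                                          continuous = c("age", "WHR", "BMI",
                                                         "BP", "BAG"),
                                          variables = study_variables()) {
  scaling <- match.arg(scaling)
  clinical <- c(age = 30, WHR = 0.05, BMI = 5, BP = 20, BAG = 6)
  variables <- intersect(variables, names(cohort))
  out <- cohort[, variables, drop = FALSE]
  for (v in variables) {
    x <- as.numeric(out[[v]])
    if (v %in% continuous) {
      if (scaling == "clinical") {
        if (is.na(clinical[v]))
          stop("encode_for_structure_learning: no clinical scale for '", v, "'")
        x <- x / clinical[[v]]
      } else {
        s <- stats::sd(x)
        x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
      }
    }
    out[[v]] <- x
  }
  out
}

#' Learn a weighted adjacency matrix under acyclicity and edge constraints
#'
#' Minimizes the least-squares reconstruction loss
#' `||X - XW||_F^2 / (2n) + l1_penalty * ||W||_1` subject to `h(W) = 0`,
#' via the standard augmented-Lagrangian schedule (penalty `rho` starts at
#' 1 and is multiplied by 10 whenever `h` fails to shrink by the progress
#' ratio; the inner problem is solved by L-BFGS-B on the positive/negative
#' part split of `W`). Forbidden entries are excluded from the parameter
#' vector, so they are exactly zero throughout the optimization. The run is
#' deterministic for fixed data and options.
#'
#' @param data numeric table, already encoded/standardized
#'   (see [encode_for_structure_learning()]).
#' @param constraints a [default_constraints()] set matching the columns,
#'   or `NULL` for none.
#' @param l1_penalty nonnegative L1 weight (default 0.1).
#' @param opts list overriding the defaults `rho_init = 1`,
#'   `rho_max = 1e16`, `h_tol = 1e-8`, `max_dual_iter = 100`,
#'   `progress_ratio = 0.25`, `optim_maxit = 500`.
#' @return object of class `weighted_adjacency`: matrix `W` with variable
#'   dimnames, final `h`, dual `iterations`.
#' @export
learn_weighted_adjacency <- function(data, constraints = NULL,
                                     l1_penalty = 0.1, opts = list()) {
  X <- as.matrix(data)
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("learn_weighted_adjacency: 'data' must be finite numeric")
  X <- scale(X, center = TRUE, scale = FALSE)  # the SEM has no intercepts
  d <- ncol(X); n <- nrow(X)
  if (d < 2L) stop("learn_weighted_adjacency: need at least 2 variables")
  if (l1_penalty < 0) stop("learn_weighted_adjacency: 'l1_penalty' must be >= 0")
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("V", seq_len(d))
  o <- utils::modifyList(list(rho_init = 1, rho_max = 1e16, h_tol = 1e-8,
                              max_dual_iter = 100L, progress_ratio = 0.25,
                              optim_maxit = 500L), opts)
  forbidden <- matrix(FALSE, d, d)
  if (!is.null(constraints)) {
    stopifnot(inherits(constraints, "constraint_set"))
    if (!identical(constraints$variables, vars))
      stop("learn_weighted_adjacency: constraint variables do not match ",
           "data columns")
    forbidden <- constraints$forbidden
  }
  diag(forbidden) <- TRUE
  free <- which(!forbidden)
  nf <- length(free)
  make_W <- function(theta) {
    W <- matrix(0, d, d)
    W[free] <- theta[seq_len(nf)] - theta[nf + seq_len(nf)]
    W
  }
  obj <- function(theta, rho, alpha) {
    W <- make_W(theta)
    R <- X - X %*% W
    E <- as.matrix(Matrix::expm(W * W))
    h <- sum(diag(E)) - d
    f <- sum(R^2) / (2 * n) + l1_penalty * sum(theta) +
      0.5 * rho * h * h + alpha * h
    G <- -crossprod(X, R) / n + (rho * h + alpha) * (2 * W * t(E))
    attr(f, "grad") <- c(G[free], -G[free]) + l1_penalty
    f
  }
  grad_cache <- NULL
  fn <- function(theta, rho, alpha) {
    val <- obj(theta, rho, alpha)
    grad_cache <<- attr(val, "grad")
    as.numeric(val)
  }
  gr <- function(theta, rho, alpha) grad_cache
  theta <- rep(0, 2 * nf)
  rho <- o$rho_init; alpha <- 0; h <- Inf
  iters <- 0L
  for (it in seq_len(o$max_dual_iter)) {
    iters <- it
    repeat {
      fit <- stats::optim(theta, fn, gr, rho = rho, alpha = alpha,
                          method = "L-BFGS-B", lower = 0,
                          control = list(maxit = o$optim_maxit))
      h_new <- acyclicity_h(make_W(fit$par))
      if (h_new > o$progress_ratio * h && rho < o$rho_max) rho <- rho * 10
      else break
    }
    theta <- fit$par
    h <- h_new
    alpha <- alpha + rho * h
    if (h <= o$h_tol || rho >= o$rho_max) break
  }
  if (h > o$h_tol)
    stop(sprintf(paste0("learn_weighted_adjacency: failed to reach the ",
                        "acyclicity tolerance (final h = %.3e > %.1e)"),
                 h, o$h_tol))
  W <- make_W(theta)
  dimnames(W) <- list(vars, vars)
  structure(list(W = W, h = h, iterations = iters, l1_penalty = l1_penalty),
            class = "weighted_adjacency")
}

#' Directed acyclic graph structure
#'
#' @param nodes node names.
#' @param edges data.frame with columns `parent`, `child` and optionally
#'   `weight`.
#' @param threshold pruning threshold recorded with the structure.
#' @return object of class `dag_structure`. Construction fails if the edge
#'   set is cyclic.
#' @export
dag_structure <- function(nodes, edges, threshold = NA_real_) {
  edges <- as.data.frame(edges)
  if (!all(c("parent", "child") %in% names(edges)))
    stop("dag_structure: 'edges' needs 'parent' and 'child' columns")
  if (!"weight" %in% names(edges)) edges$weight <- rep(NA_real_, nrow(edges))
  bad <- setdiff(c(edges$parent, edges$child), nodes)
  if (length(bad)) stop("dag_structure: edge endpoint(s) not in 'nodes': ",
                        paste(unique(bad), collapse = ", "))
  g <- igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                     directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g))
    stop("dag_structure: the edge set contains a cycle")
  structure(list(nodes = nodes,
                 edges = edges[, c("parent", "child", "weight")],
                 threshold = threshold,
                 order = nodes[igraph::topo_sort(g)]),
            class = "dag_structure")
}

#' @export
print.dag_structure <- function(x, ...) {
  cat("DAG:", length(x$nodes), "nodes,", nrow(x$edges), "edges")
  if (!is.na(x$threshold)) cat(" (pruning threshold", x$threshold, ")")
  cat("\n")
  if (nrow(x$edges))
    cat(paste0("  ", x$edges$parent, " -> ", x$edges$child,
               ifelse(is.na(x$edges$weight), "",
                      sprintf(" (%.3f)", x$edges$weight)), "\n"), sep = "")
  invisible(x)
}

dag_parents <- function(dag, node) dag$edges$parent[dag$edges$child == node]

#' Prune weak edges from a weighted adjacency matrix
#'
#' Keeps edges with `|w| > threshold` and verifies that the result is
#' acyclic (for `h` tolerances above zero a too-small threshold can retain
#' a numerical cycle).
#'
#' @param W a [learn_weighted_adjacency()] result (or plain matrix).
#' @param threshold nonnegative absolute-weight cut-off.
#' @return a [dag_structure()] carrying the retained weights and threshold.
#' @export
prune_edges <- function(W, threshold) {
  if (threshold < 0) stop("prune_edges: 'threshold' must be >= 0")
  M <- if (inherits(W, "weighted_adjacency")) W$W else as.matrix(W)
  keep <- which(abs(M) > threshold, arr.ind = TRUE)
  edges <- data.frame(parent = rownames(M)[keep[, 1]],
                      child = colnames(M)[keep[, 2]],
                      weight = M[keep])
  tryCatch(dag_structure(rownames(M), edges, threshold = threshold),
           error = function(e) stop("prune_edges: pruned graph is cyclic at ",
                                    "threshold ", threshold,
                                    "; use a larger threshold"))
}

#' Structural Hamming distance between two DAGs
#'
#' Number of edge insertions, deletions and reversals separating the two
#' structures (a reversed edge counts once).
#'
#' @param dag_a,dag_b [dag_structure()] objects over the same node set.
#' @return nonnegative integer.
#' @export
structural_hamming_distance <- function(dag_a, dag_b) {
  key <- function(d) paste(d$edges$parent, d$edges$child, sep = "->")
  a <- key(dag_a); b <- key(dag_b)
  rev_b <- paste(dag_b$edges$child, dag_b$edges$parent, sep = "->")
  reversed <- sum(setdiff(a, b) %in% rev_b)
  length(setdiff(a, b)) + length(setdiff(b, a)) - reversed
}

#' Choose the pruning threshold by cross-validated node AUC
#'
#' For each candidate threshold the pruned DAG is fitted and validated by
#' [crossvalidated_auc()]; the chosen threshold maximizes the mean of the
#' average node AUC and the target-node (BAG) AUC, ties breaking toward the
#' larger threshold (sparser graph).
#'
#' @param W a [learn_weighted_adjacency()] result.
#' @param candidate_thresholds numeric candidates
#'   (default `c(0.05, 0.1, 0.15, 0.2, 0.3)`).
#' @param disc_data discretized cohort (see [discretize_cohort()]).
#' @param cv_opts list: `k` (10), `repeats` (10), `seed` (1),
#'   `pseudo_count` (1), `target` ("BAG").
#' @return list with `threshold`, the winning [dag_structure()] as `dag`,
#'   and a per-candidate `report` data.frame.
#' @export
select_threshold <- function(W, candidate_thresholds = c(0.05, 0.1, 0.15, 0.2, 0.3),
                             disc_data, cv_opts = list()) {
  if (!length(candidate_thresholds)) stop("select_threshold: no candidates")
  o <- utils::modifyList(list(k = 10L, repeats = 10L, seed = 1L,
                              pseudo_count = 1, target = "BAG"), cv_opts)
  report <- data.frame(threshold = candidate_thresholds, n_edges = NA_integer_,
                       mean_auc = NA_real_, target_auc = NA_real_,
                       score = NA_real_, valid = FALSE)
  dags <- vector("list", length(candidate_thresholds))
  for (i in seq_along(candidate_thresholds)) {
    dag <- tryCatch(prune_edges(W, candidate_thresholds[i]),
                    error = function(e) NULL)
    if (is.null(dag)) next
    cv <- crossvalidated_auc(dag, disc_data, k = o$k, repeats = o$repeats,
                             seed = o$seed, pseudo_count = o$pseudo_count)
    report$n_edges[i] <- nrow(dag$edges)
    report$mean_auc[i] <- cv$average
    report$target_auc[i] <- cv$report$auc_mean[cv$report$node == o$target]
    report$score[i] <- mean(c(report$mean_auc[i], report$target_auc[i]),
                            na.rm = TRUE)
    report$valid[i] <- TRUE
    dags[[i]] <- dag
  }
  if (!any(report$valid)) stop("select_threshold: no candidate yields a valid DAG")
  ok <- which(report$valid)
  best <- ok[order(-report$score[ok], -report$threshold[ok])][1L]
  list(threshold = candidate_thresholds[best], dag = dags[[best]],
       report = report)
}

#' Export a DAG (optionally with edge signs) to Graphviz DOT
#'
#' Positive associations are drawn red, negative blue, nonlinear dashed,
#' mirroring the study-style network figure.
#'
#' @param dag a [dag_structure()].
#' @param path output file.
#' @param signs optional data.frame from [classify_all_edges()].
#' @export
export_dot <- function(dag, path, signs = NULL) {
  lines <- c("digraph G {", paste0('  "', dag$nodes, '";'))
  for (i in seq_len(nrow(dag$edges))) {
    e <- dag$edges[i, ]
    attrs <- character()
    if (!is.null(signs)) {
      s <- signs$label[signs$parent == e$parent & signs$child == e$child]
      if (length(s) == 1L)
        attrs <- switch(s,
                        positive = 'color="red"',
                        negative = 'color="blue"',
                        nonlinear = 'style="dashed"')
    }
    lines <- c(lines, paste0('  "', e$parent, '" -> "', e$child, '"',
                             if (length(attrs)) paste0(" [", attrs, "]"),
                             ";"))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
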