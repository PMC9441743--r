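# Independent oracles used across the suite. These deliberately avoid the
# package's own inference/optimization code paths.

# Taylor-series matrix exponential: sum_{k=0}^{K} M^k / k!
series_expm <- function(M, K = 60L) {
  out <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in seq_len(K)) {
    term <- term %*% M / k
    out <- out + term
  }
  out
}

series_h <- function(W) sum(diag(series_expm(W * W))) - nrow(W)

# Random Bayesian network over d nodes with given cardinality: random
# upper-triangular DAG (edge prob 0.5) and Dirichlet(1) CPT rows.
random_bn <- function(d = 5L, card = 3L, edge_prob = 0.5) {
  nodes <- paste0("N", seq_len(d))
  edges <- NULL
  for (j in seq_len(d)[-1]) for (i in seq_len(j - 1L))
    if (stats::runif(1) < edge_prob)
      edges <- rbind(edges, data.frame(parent = nodes[i], child = nodes[j]))
  if (is.null(edges))
    edges <- data.frame(parent = character(), child = character())
  dag <- dag_structure(nodes, edges)
  model <- list(dag = dag, nodes = list(), order = dag$order)
  for (nm in nodes) {
    par <- dag$edges$parent[dag$edges$child == nm]
    nr <- card^length(par)
    cpt <- matrix(stats::rgamma(nr * card, 1), nr, card)
    cpt <- cpt / rowSums(cpt)
    colnames(cpt) <- as.character(seq_len(card) - 1L)
    model$nodes[[nm]] <- list(states = as.character(seq_len(card) - 1L),
                              parents = par, cpt = cpt)
  }
  class(model) <- "bn_model"
  model
}

# Full-joint probability of every complete assignment (rows of the state
# grid), by direct multiplication of CPD entries.
enum_joint <- function(model) {
  cards <- vapply(model$nodes, function(nd) length(nd$states), integer(1))
  grid <- expand.grid(lapply(cards, seq_len))       # 1-based state indices
  p <- rep(1, nrow(grid))
  for (nm in names(model$nodes)) {
    nd <- model$nodes[[nm]]
    row <- rep(1L, nrow(grid)); mult <- 1L
    for (pp in nd$parents) {
      row <- row + (grid[[pp]] - 1L) * mult
      mult <- mult * cards[[pp]]
    }
    p <- p * nd$cpt[cbind(row, grid[[nm]])]
  }
  cbind(grid, prob = p)
}

# P(target | evidence) by brute-force enumeration; evidence is a named list
# of 1-based state indices.
enum_conditional <- function(model, target, evidence = list()) {
  j <- enum_joint(model)
  keep <- rep(TRUE, nrow(j))
  for (v in names(evidence)) keep <- keep & j[[v]] == evidence[[v]]
  j <- j[keep, ]
  probs <- tapply(j$prob, j[[target]], sum)
  out <- numeric(length(model$nodes[[target]]$states))
  out[as.integer(names(probs))] <- probs
  out / sum(out)
}

# P(target | do(node = idx)) by truncated factorization: drop the do-node's
# factor, clamp its value, enumerate the rest.
enum_do <- function(model, target, do_node, do_idx) {
  clamped <- model
  card <- length(model$nodes[[do_node]]$states)
  cpt <- matrix(0, 1L, card,
                dimnames = list(NULL, model$nodes[[do_node]]$states))
  cpt[1L, do_idx] <- 1
  clamped$nodes[[do_node]] <- list(states = model$nodes[[do_node]]$states,
                                   parents = character(), cpt = cpt)
  enum_conditional(clamped, target)
}

state_of <- function(model, node, idx) model$nodes[[node]]$states[idx]

# a fixed confounded triangle Z -> X, Z -> Y, X -> Y with random CPTs
random_triangle <- function(card = 3L) {
  dag <- dag_structure(c("Z", "X", "Y"),
                       data.frame(parent = c("Z", "Z", "X"),
                                  child = c("X", "Y", "Y")))
  mk <- function(nr) {
    p <- matrix(stats::rgamma(nr * card, 1), nr, card)
    p <- p / rowSums(p)
    colnames(p) <- as.character(seq_len(card) - 1L)
    p
  }
  structure(list(dag = dag, nodes = list(
    Z = list(states = as.character(0:(card - 1)), parents = character(),
             cpt = mk(1)),
    X = list(states = as.character(0:(card - 1)), parents = "Z",
             cpt = mk(card)),
    Y = list(states = as.character(0:(card - 1)), parents = c("Z", "X"),
             cpt = mk(card^2))), order = dag$order), class = "bn_model")
}
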