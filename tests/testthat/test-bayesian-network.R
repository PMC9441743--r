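single_node_dag <- dag_structure("X", data.frame(parent = character(),
                                                 child = character()))

test_that("Dirichlet estimation matches the posterior-mean formula", {
  data <- data.frame(X = c(rep(0, 7), rep(1, 3)))
  m0 <- fit_cpds(single_node_dag, data, pseudo_count = 0)
  expect_equal(as.numeric(m0$nodes$X$cpt), c(0.7, 0.3))
  m1 <- fit_cpds(single_node_dag, data, pseudo_count = 1)
  expect_equal(as.numeric(m1$nodes$X$cpt), c(8 / 12, 4 / 12))
})

test_that("every fitted CPD row is a normalized distribution", {
  set.seed(19)
  co <- generate_scm_cohort(default_study_scm(), 500, seed = 19)
  co$BAG <- stats::rnorm(500, 0, 4)
  disc <- discretize_cohort(co)
  dag <- scm_dag(default_study_scm())
  m <- fit_cpds(dag, disc, pseudo_count = 1)
  for (nd in m$nodes) {
    expect_true(all(nd$cpt >= 0))
    expect_true(all(abs(rowSums(nd$cpt) - 1) < 1e-9))
  }
})

test_that("unseen parent configurations fall back to the uniform prior", {
  dag <- dag_structure(c("P", "C"), data.frame(parent = "P", child = "C"))
  data <- data.frame(P = c(0, 0, 0), C = c(0, 1, 1))
  m <- fit_cpds(dag, data, pseudo_count = 1, states = list(P = 0:1, C = 0:1))
  expect_equal(as.numeric(m$nodes$C$cpt[2, ]), c(0.5, 0.5))  # P=1 unseen
  expect_error(fit_cpds(dag, data, pseudo_count = 0,
                        states = list(P = 0:1, C = 0:1)), "undefined")
})

test_that("variable elimination matches brute-force enumeration", {
  set.seed(20)
  for (case in 1:15) {
    m <- random_bn(d = 5, card = 3)
    tgt <- sample(names(m$nodes), 1)
    ev_nodes <- sample(setdiff(names(m$nodes), tgt), sample(0:3, 1))
    ev_idx <- stats::setNames(lapply(ev_nodes, function(x) sample(3, 1)),
                              ev_nodes)
    ev <- stats::setNames(lapply(seq_along(ev_idx), function(k)
      state_of(m, names(ev_idx)[k], ev_idx[[k]])), names(ev_idx))
    q <- query_conditional(m, tgt, ev)
    expect_equal(sum(q$probs), 1, tolerance = 1e-12)
    expect_equal(unname(q$probs), enum_conditional(m, tgt, ev_idx),
                 tolerance = 1e-9)
  }
})

test_that("local-Markov shortcuts hold exactly", {
  set.seed(21)
  m <- random_bn(d = 4, card = 3)
  # empty evidence on a root: its marginal CPD row
  roots <- names(m$nodes)[vapply(m$nodes, function(nd)
    length(nd$parents) == 0L, logical(1))]
  r <- roots[1]
  expect_equal(unname(query_conditional(m, r)$probs),
               as.numeric(m$nodes[[r]]$cpt[1, ]), tolerance = 1e-12)
  # a leaf given all its parents: the matching CPD row exactly
  dag <- dag_structure(c("A", "B", "L"),
                       data.frame(parent = c("A", "B"), child = c("L", "L")))
  ml <- random_bn(d = 3, card = 3)
  ml$dag <- dag
  ml$nodes <- list(
    A = list(states = as.character(0:2), parents = character(),
             cpt = ml$nodes$N1$cpt[1, , drop = FALSE]),
    B = list(states = as.character(0:2), parents = character(),
             cpt = ml$nodes$N1$cpt[1, , drop = FALSE]),
    L = list(states = as.character(0:2), parents = c("A", "B"),
             cpt = {
               p <- matrix(stats::rgamma(27, 1), 9, 3)
               p <- p / rowSums(p); colnames(p) <- as.character(0:2); p
             }))
  q <- query_conditional(ml, "L", list(A = "2", B = "1"))
  row <- 3 + 3 * 1   # A index 3, B index 2, first parent fastest
  expect_equal(unname(q$probs), as.numeric(ml$nodes$L$cpt[row, ]),
               tolerance = 1e-12)
})

test_that("impossible evidence is reported as such", {
  dag <- dag_structure(c("A", "B"), data.frame(parent = "A", child = "B"))
  m <- fit_cpds(dag, data.frame(A = c(0, 0, 1, 1), B = c(0, 0, 1, 1)),
                pseudo_count = 0)
  expect_error(query_conditional(m, "A", list(B = 5)), "invalid state")
  # B = 1 never co-occurs with A = 0 and pseudo_count = 0
  expect_error(query_conditional(m, "B",
                                 list(A = "0", B = "1")), "target")
  m$nodes$A$cpt[1, ] <- c(1, 0)   # A = 1 now impossible
  expect_error(query_conditional(m, "B", list(A = "1")),
               "probability zero")
})

test_that("node prediction breaks ties toward the lower state code", {
  dag <- single_node_dag
  m <- fit_cpds(dag, data.frame(X = c(0, 1)), pseudo_count = 1)
  expect_equal(as.numeric(m$nodes$X$cpt), c(0.5, 0.5))
  expect_identical(predict_node(m, "X", list())$state, "0")
})

test_that("vectorized node posteriors equal the exact conditional", {
  set.seed(22)
  m <- random_bn(d = 5, card = 3)
  data <- as.data.frame(lapply(m$nodes, function(nd)
    sample(nd$states, 20, replace = TRUE)))
  names(data) <- names(m$nodes)
  for (node in names(m$nodes)) {
    post <- node_posteriors(m, data, node)
    for (i in c(1, 7, 20)) {
      ev <- as.list(data[i, setdiff(names(data), node), drop = FALSE])
      q <- query_conditional(m, node, ev)
      expect_equal(unname(post[i, ]), unname(q$probs), tolerance = 1e-9)
    }
  }
})

test_that("cross-validated AUC separates signal nodes from independent ones", {
  set.seed(23)
  n <- 1500
  P <- sample(0:2, n, replace = TRUE)
  C <- ifelse(stats::runif(n) < 0.9, P, (P + sample(1:2, n, TRUE)) %% 3)
  X <- sample(0:2, n, replace = TRUE)          # independent of everything
  data <- data.frame(P = P, C = C, X = X)
  dag <- dag_structure(c("P", "C", "X"),
                       data.frame(parent = "P", child = "C"))
  cv <- crossvalidated_auc(dag, data, k = 10, repeats = 3, seed = 2)
  expect_equal(nrow(cv$report), 3L)
  expect_true(all(cv$report$auc_sd >= 0))
  expect_true(all(cv$report$auc_mean >= 0 & cv$report$auc_mean <= 1))
  expect_equal(cv$average, mean(cv$report$auc_mean))
  auc <- stats::setNames(cv$report$auc_mean, cv$report$node)
  expect_gt(auc["C"], 0.85)                    # 90%-agreement copy
  expect_lt(abs(auc["X"] - 0.5), 0.08)         # independent node: chance
})

test_that("fitted CPDs converge to the generating tables", {
  cpt_b <- rbind(c(0.7, 0.2, 0.1), c(0.2, 0.3, 0.5))
  spec <- scm_spec(list(
    A = scm_categorical(c(0.4, 0.6), states = 0:1),
    B = scm_cpt("A", cpt_b, states = 0:2)
  ))
  co <- generate_scm_cohort(spec, 50000, seed = 24)
  dag <- scm_dag(spec)
  m <- fit_cpds(dag, co[, c("A", "B")], pseudo_count = 1)
  expect_lt(max(abs(m$nodes$B$cpt - cpt_b)), 0.02)
  expect_lt(max(abs(as.numeric(m$nodes$A$cpt) - c(0.4, 0.6))), 0.02)
})

test_that("fitted models round-trip through JSON", {
  set.seed(25)
  co <- generate_scm_cohort(default_study_scm(), 300, seed = 25)
  co$BAG <- stats::rnorm(300, 0, 4)
  disc <- discretize_cohort(co)
  m <- fit_cpds(scm_dag(default_study_scm()), disc)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_bn_json(m, path)
  m2 <- read_bn_json(path)
  expect_equal(m2$dag$edges$parent, m$dag$edges$parent)
  q1 <- query_conditional(m, "BAG", list(BMI = 2, sex = 0))
  q2 <- query_conditional(m2, "BAG", list(BMI = 2, sex = 0))
  expect_equal(q1$probs, q2$probs, tolerance = 1e-12)
})

test_that("the enumerated joint of a fitted model sums to one", {
  set.seed(26)
  m <- random_bn(d = 6, card = 3)
  expect_equal(sum(enum_joint(m)$prob), 1, tolerance = 1e-9)
})
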