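test_that("intervening mutilates the graph and clamps the node", {
  set.seed(27)
  m <- random_triangle()
  mi <- intervene(m, "X", "1")
  expect_length(mi$nodes$X$parents, 0)
  expect_equal(as.numeric(mi$nodes$X$cpt), c(0, 1, 0))
  expect_false(any(mi$dag$edges$child == "X"))
  expect_identical(mi$nodes$Y$cpt, m$nodes$Y$cpt)   # other CPDs untouched
  # intervening on a root changes only that root's marginal
  mr <- intervene(m, "Z", "2")
  expect_equal(as.numeric(mr$nodes$Z$cpt), c(0, 0, 1))
  expect_identical(mr$dag$edges, m$dag$edges)
  expect_identical(mr$nodes$X$cpt, m$nodes$X$cpt)
  # double intervention: last assignment wins, idempotent
  m2 <- intervene(intervene(m, "X", "0"), "X", "2")
  expect_identical(m2$nodes$X, intervene(m, "X", "2")$nodes$X)
  expect_identical(m2$interventions, list(X = "2"))
  # mutilated model still satisfies the model invariants
  for (nd in m2$nodes) expect_true(all(abs(rowSums(nd$cpt) - 1) < 1e-12))
  expect_equal(sum(enum_joint(m2)$prob), 1, tolerance = 1e-9)
  expect_error(intervene(m, "Q", "0"), "unknown node")
  expect_error(intervene(m, "X", "9"), "invalid state")
})

test_that("interventions match the backdoor-adjustment oracle", {
  set.seed(28)
  for (case in 1:15) {
    m <- random_triangle()
    x_idx <- sample(3, 1)
    got <- interventional_distribution(m, "Y", "X", state_of(m, "X", x_idx))
    expect_identical(got$mode, "interventional")
    expect_equal(sum(got$probs), 1, tolerance = 1e-12)
    # backdoor: sum_z P(Y | X = x, Z = z) P(Z = z), computed from the CPTs
    pz <- as.numeric(m$nodes$Z$cpt[1, ])
    bd <- numeric(3)
    for (z in 1:3)
      bd <- bd + pz[z] * as.numeric(m$nodes$Y$cpt[z + 3 * (x_idx - 1), ])
    expect_equal(unname(got$probs), bd, tolerance = 1e-9)
    # and the truncated-factorization enumeration agrees too
    expect_equal(unname(got$probs), enum_do(m, "Y", "X", x_idx),
                 tolerance = 1e-9)
  }
})

test_that("root-node interventions equal observation; non-ancestors have no effect", {
  set.seed(29)
  m <- random_triangle()
  for (z in as.character(0:2)) {
    obs <- query_conditional(m, "Y", list(Z = z))
    int <- interventional_distribution(m, "Y", "Z", z)
    expect_equal(unname(obs$probs), unname(int$probs), tolerance = 1e-12)
  }
  # do on a non-ancestor leaves the target at its marginal
  int <- interventional_distribution(m, "Z", "Y", "1")
  expect_equal(unname(int$probs), as.numeric(m$nodes$Z$cpt[1, ]),
               tolerance = 1e-12)
})

test_that("observe-vs-intervene tables are normalized and coherent", {
  set.seed(30)
  m <- random_triangle()
  tab <- observe_vs_intervene_table(m, "X", "Y")
  pcols <- as.matrix(tab[, as.character(0:2)])
  expect_equal(unname(rowSums(pcols)), rep(1, nrow(tab)), tolerance = 1e-9)
  expect_equal(nrow(tab), 6L)                       # 3 states x 2 modes
  # law of total probability on the observational column
  px <- vapply(as.character(0:2), function(s)
    query_conditional(m, "X", list())$probs[s], numeric(1))
  marg_from_obs <- colSums(pcols[tab$mode == "observational", ] * px)
  marg <- query_conditional(m, "Y", list())$probs
  expect_equal(unname(marg_from_obs), unname(marg), tolerance = 1e-9)
  # for a root risk factor the two modes coincide
  tabz <- observe_vs_intervene_table(m, "Z", "Y")
  expect_equal(tabz[tabz$mode == "observational", as.character(0:2)],
               tabz[tabz$mode == "interventional", as.character(0:2)],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(observe_vs_intervene_table(m, "Y", "Y"), "must differ")
})

test_that("confounding separates observation from intervention on study data", {
  # WHR confounds the BMI -> BAG edge in the generating model
  co <- generate_scm_cohort(default_study_scm("strong"), 4000, seed = 31)
  disc <- discretize_cohort(co)
  m <- fit_cpds(scm_dag(default_study_scm()), disc, pseudo_count = 1)
  tab <- observe_vs_intervene_table(m, "BMI", "BAG")
  states <- m$nodes$BAG$states
  l1 <- vapply(unique(tab$state), function(s) {
    o <- as.numeric(tab[tab$state == s & tab$mode == "observational", states])
    i <- as.numeric(tab[tab$state == s & tab$mode == "interventional", states])
    sum(abs(o - i))
  }, numeric(1))
  expect_gt(max(l1), 0.01)
})

test_that("edge signs follow the expected-state monotonicity rule", {
  mk_model <- function(cpt) {
    dag <- dag_structure(c("P", "C"), data.frame(parent = "P", child = "C"))
    colnames(cpt) <- as.character(0:2)
    structure(list(dag = dag, nodes = list(
      P = list(states = as.character(0:2), parents = character(),
               cpt = matrix(rep(1 / 3, 3), 1, dimnames = list(NULL, 0:2))),
      C = list(states = as.character(0:2), parents = "P", cpt = cpt)),
      order = dag$order), class = "bn_model")
  }
  inc <- rbind(c(0.8, 0.15, 0.05), c(0.3, 0.4, 0.3), c(0.05, 0.15, 0.8))
  expect_identical(classify_edge_sign(mk_model(inc), "P", "C")$label,
                   "positive")
  expect_identical(classify_edge_sign(mk_model(inc[3:1, ]), "P", "C")$label,
                   "negative")
  vshape <- rbind(c(0.1, 0.1, 0.8), c(0.8, 0.1, 0.1), c(0.1, 0.1, 0.8))
  expect_identical(classify_edge_sign(mk_model(vshape), "P", "C")$label,
                   "nonlinear")
  flat <- matrix(rep(c(0.2, 0.5, 0.3), each = 3), 3)
  s <- classify_edge_sign(mk_model(flat), "P", "C")
  expect_identical(s$label, "nonlinear")
  expect_true(s$zero_effect)
  expect_error(classify_edge_sign(mk_model(inc), "C", "P"), "not in the DAG")
})

test_that("classify_all_edges labels every DAG edge", {
  set.seed(36)
  m <- random_triangle()
  labs <- classify_all_edges(m)
  expect_equal(nrow(labs), 3L)
  expect_true(all(labs$label %in% c("positive", "negative", "nonlinear")))
})
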