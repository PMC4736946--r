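test_that("transition matrix matches the closed form and the matrix exponential", {
  m <- mk_model(0.5, 0.5)
  expect_equal(unname(mk_transition_matrix(m, 0)), diag(2))
  expect_equal(mk_transition_matrix(m, 1)[1, 1], (1 + exp(-1)) / 2,
               tolerance = 1e-12)
  # long-branch limit: rows approach the stationary distribution
  m2 <- mk_model(0.3, 0.9, "Mk2")
  P_inf <- mk_transition_matrix(m2, 1e6)
  expect_equal(unname(P_inf[1, ]), c(0.75, 0.25), tolerance = 1e-9)
  expect_equal(unname(P_inf[2, ]), c(0.75, 0.25), tolerance = 1e-9)
  # dual route: closed form vs numerical matrix exponential
  for (pars in list(c(0.2, 0.7), c(1.5, 0.1), c(0.05, 0.05))) {
    expect_equal(unname(mk_transition_matrix(mk_model(pars[1], pars[2],
                                                      "Mk2"), 0.8)),
                 unname(oracle_pmat(pars[1], pars[2], 0.8)), tolerance = 1e-9)
  }
  expect_true(all(abs(rowSums(mk_transition_matrix(m2, 2)) - 1) < 1e-12))
  expect_error(mk_transition_matrix(m, -1), ">= 0")
})

test_that("pruning likelihood equals the enumeration oracle on small trees", {
  set.seed(101)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    tr <- ape::rphylo(n, 1, 0)
    tr$tip.label <- paste0("t", seq_len(n))
    states <- setNames(sample(c(0L, 1L), n, replace = TRUE), tr$tip.label)
    if (i %% 3 == 0) states[sample(n, 1)] <- NA  # missing tip as flat partial
    if (all(is.na(states))) states[1] <- 1L
    q01 <- runif(1, 0.05, 2); q10 <- runif(1, 0.05, 2)
    expect_equal(tree_loglik(tr, states, mk_model(q01, q10, "Mk2")),
                 oracle_mk_loglik(tr, states, q01, q10), tolerance = 1e-10)
  }
})

test_that("degenerate likelihoods marginalise correctly", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  m <- mk_model(0.4, 0.4)
  # single scored tip: marginalising the chain from a uniform root gives 1/2
  expect_equal(tree_loglik(tr, c(A = 1, B = NA, C = NA), m), log(0.5))
  # zero-length branches, all present: only the root prior remains
  tz <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  expect_equal(tree_loglik(tz, c(A = 1, B = 1, C = 1), m), log(0.5))
  expect_error(tree_loglik(tr, c(A = NA, B = NA, C = NA), m), "missing")
})

test_that("likelihood-ratio selection controls type-I error and has power", {
  expect_equal(qchisq(0.95, 1), 3.841459, tolerance = 1e-6)
  set.seed(7)
  tr <- ape::rphylo(48, 1, 0)
  depth <- max(ape::node.depth.edgelength(tr))
  q <- 1.5 / depth
  sim <- sim_mk_traits(tr, q, q, n_traits = 60, seed = 70)
  null_picks <- vapply(1:60, function(j) {
    st <- setNames(unclass(sim$matrix)[, j], rownames(sim$matrix))
    if (length(unique(st)) < 2) return(NA)
    fit_and_select(tr, st)$kind == "Mk2"
  }, logical(1))
  expect_lt(mean(null_picks, na.rm = TRUE), 0.15)  # near-nominal false positives
  # strong asymmetry is detected
  tr2 <- ape::rphylo(128, 1, 0)
  d2 <- max(ape::node.depth.edgelength(tr2))
  sim2 <- sim_mk_traits(tr2, 2 / d2 * 4, 0.1 / d2 * 4, n_traits = 25, seed = 71)
  alt_picks <- vapply(1:25, function(j) {
    st <- setNames(unclass(sim2$matrix)[, j], rownames(sim2$matrix))
    if (length(unique(st)) < 2) return(NA)
    fit_and_select(tr2, st)$kind == "Mk2"
  }, logical(1))
  expect_gte(mean(alt_picks, na.rm = TRUE), 0.6)
})

test_that("marginal node probabilities match the enumeration oracle", {
  set.seed(55)
  for (i in 1:6) {
    n <- sample(4:5, 1)
    tr <- ape::rphylo(n, 1, 0)
    tr$tip.label <- paste0("t", seq_len(n))
    states <- setNames(sample(c(0L, 1L), n, replace = TRUE), tr$tip.label)
    q01 <- runif(1, 0.1, 1.5); q10 <- runif(1, 0.1, 1.5)
    probs <- marginal_node_probs(tr, states, mk_model(q01, q10, "Mk2"))
    for (node in seq.int(n + 1L, n + tr$Nnode)) {
      expect_equal(probs[[as.character(node)]],
                   oracle_mk_marginal(tr, states, q01, q10, node),
                   tolerance = 1e-10)
    }
  }
})

test_that("marginals respect unanimity and symmetry", {
  tr <- ape::rphylo(16, 1, 0)
  all1 <- setNames(rep(1L, 16), tr$tip.label)
  probs <- marginal_node_probs(tr, all1, mk_model(0.01, 0.01))
  expect_true(all(probs > 0.99))
  # mirrored states on a mirrored tree put the root at exactly 1/2
  sym <- balanced_quartet()
  p <- marginal_node_probs(sym, c(A = 1, B = 1, C = 0, D = 0), mk_model(0.3, 0.3))
  expect_equal(p[["5"]], 0.5, tolerance = 1e-12)
})

test_that("root state is recovered on simulated traits", {
  set.seed(12)
  tr <- ape::rphylo(64, 1, 0)
  depth <- max(ape::node.depth.edgelength(tr))
  q <- 0.05 * 4 / depth  # a slow trait: ~0.2 expected changes root-to-tip
  sim <- sim_mk_traits(tr, q, q, n_traits = 50, seed = 13)
  root <- as.character(65)
  hits <- vapply(1:50, function(j) {
    st <- setNames(unclass(sim$matrix)[, j], rownames(sim$matrix))
    if (length(unique(st)) < 2) return(NA)  # constant: root is trivially known
    model <- fit_and_select(tr, st)
    p_root <- marginal_node_probs(tr, st, model)[[root]]
    (p_root > 0.5) == (sim$node_states[root, j] == 1)
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.8)
})

test_that("aggregation across a tree sample matches a brute-force loop", {
  set.seed(31)
  sim <- sim_tree_sample(n_taxa = 10, n_trees = 10, seed = 31,
                         root_nni_prob = 0.4)
  states <- setNames(unclass(sim_mk_traits(sim$true_tree, 0.4, 0.4, 1,
                                           seed = 32)$matrix)[, 1],
                     sim$true_tree$tip.label)
  states[sim$outgroup] <- NA
  con <- majority_consensus(sim$sample, 0.5, sim$outgroup)
  agg <- aggregate_over_sample(sim$sample, states, con, outgroup = sim$outgroup)
  expect_true(all(agg$combined <= agg$clade_pp + 1e-12, na.rm = TRUE))
  expect_equal(agg$combined, agg$mean_p_present * agg$clade_pp)
  # brute force: per clade, loop trees, test monophyly, average the marginal
  for (ci in seq_len(nrow(agg))) {
    taxa <- strsplit(agg$members[ci], ";", fixed = TRUE)[[1]]
    ps <- c()
    for (tr in sim$sample) {
      tr <- ape::root(tr, outgroup = sim$outgroup, resolve.root = TRUE)
      mrca <- ape::getMRCA(tr, taxa)
      if (!setequal(ape::extract.clade(tr, mrca)$tip.label, taxa)) next
      model <- fit_and_select(tr, states)
      ps <- c(ps, marginal_node_probs(tr, states, model)[[as.character(mrca)]])
    }
    expect_equal(agg$n_trees[ci], length(ps))
    if (length(ps)) {
      expect_equal(agg$mean_p_present[ci], mean(ps), tolerance = 1e-9)
      expect_equal(agg$clade_pp[ci], length(ps) / 10)
    }
  }
})

test_that("corpus thresholds are strict at 50% and inclusive at 70%", {
  res <- data.frame(trait = c("t1", "t2", "t3", "t4"),
                    clade = "root",
                    combined = c(0.50, 0.69, 0.70, 0.93))
  out <- ancestral_corpora(res)
  expect_equal(out$inferred, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$secure, c(FALSE, FALSE, TRUE, TRUE))
  corp <- attr(out, "corpora")$root
  expect_setequal(corp$inferred, c("t2", "t3", "t4"))
  expect_setequal(corp$secure, c("t3", "t4"))
  # the product rule of the combined score
  expect_equal(0.9 * 0.77, 0.693)
})
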