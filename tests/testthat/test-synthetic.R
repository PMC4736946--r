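test_that("tree-sample generator is seeded, validated and shaped as configured", {
  sim <- sim_tree_sample(n_taxa = 15, n_trees = 20, seed = 3)
  expect_length(sim$sample, 20)
  expect_true(sim$outgroup %in% sim$sample[[1]]$tip.label)
  expect_silent(validate_tree_sample(sim$sample))
  sim2 <- sim_tree_sample(n_taxa = 15, n_trees = 20, seed = 3)
  expect_identical(ape::write.tree(sim$sample), ape::write.tree(sim2$sample))

  one <- sim_tree_sample(n_taxa = 10, n_trees = 1, seed = 4, root_nni_prob = 0,
                         jitter_sd = 0)
  expect_equal(ape::write.tree(one$sample[[1]]), ape::write.tree(one$true_tree))

  # no perturbation: every clade of the true tree has frequency 1
  frozen <- sim_tree_sample(n_taxa = 10, n_trees = 12, seed = 5,
                            root_nni_prob = 0, jitter_sd = 0.1)
  kids <- ape::extract.clade(frozen$true_tree,
                             ape::getMRCA(frozen$true_tree,
                                          paste0("s0", 1:3)))$tip.label
  if (length(kids) >= 2)
    expect_equal(clade_frequency(frozen$sample, kids, frozen$outgroup), 1)
})

test_that("root-adjacent perturbation lowers deep-clade frequencies into range", {
  freqs <- vapply(1:10, function(seed) {
    sim <- sim_tree_sample(n_taxa = 20, n_trees = 40, seed = seed,
                           root_nni_prob = 0.25)
    tr <- sim$true_tree
    n <- ape::Ntip(tr)
    root_kids <- tr$edge[tr$edge[, 1] == n + 1L, 2]
    ing_root <- root_kids[root_kids > n][1]
    deep_kids <- tr$edge[tr$edge[, 1] == ing_root, 2]
    deep <- deep_kids[deep_kids > n][1]
    taxa <- ape::extract.clade(tr, deep)$tip.label
    clade_frequency(sim$sample, taxa, sim$outgroup)
  }, numeric(1))
  expect_gte(mean(freqs >= 0.6 & freqs <= 0.95), 0.7)
  expect_true(mean(freqs) > 0.6 && mean(freqs) < 0.95)
})

test_that("Mk trait generator matches its frozen and stationary limits", {
  tr <- ape::rphylo(12, 1, 0)
  frozen <- sim_mk_traits(tr, 0, 0, n_traits = 5, seed = 1)
  for (j in 1:5)
    expect_length(unique(unclass(frozen$matrix)[, j]), 1)
  expect_identical(unclass(sim_mk_traits(tr, 0.5, 0.2, 10, seed = 2)$matrix),
                   unclass(sim_mk_traits(tr, 0.5, 0.2, 10, seed = 2)$matrix))
  # long branches: prevalence converges to the stationary frequency
  long <- tr
  long$edge.length <- long$edge.length * 500
  sim <- sim_mk_traits(long, 0.6, 0.2, n_traits = 1000, seed = 3)
  expect_equal(mean(unclass(sim$matrix)), 0.75, tolerance = 0.03)
  # generated matrices pass the trait validators
  expect_s3_class(sim$matrix, "trait_matrix")
})

test_that("threshold traits hit the requested prevalence exactly", {
  tr <- ape::rphylo(20, 1, 0)
  for (k in c(1, 10, 19))
    expect_equal(sum(sim_threshold_trait(tr, k, seed = k)), k)
  expect_error(sim_threshold_trait(tr, 20), "k_present")
  expect_identical(sim_threshold_trait(tr, 7, seed = 9),
                   sim_threshold_trait(tr, 7, seed = 9))
})

test_that("on a star tree the threshold-Brownian trait degenerates to a shuffle", {
  # star topology: tip values are i.i.d., so the rank-cut trait is a
  # uniformly random k-subset — exactly the shuffle null's law
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1);")
  subsets <- vapply(1:600, function(r)
    paste(sim_threshold_trait(star, 2, seed = r), collapse = ""), character(1))
  tab <- table(subsets)
  expect_equal(length(tab), 6)  # all C(4,2) arrangements occur
  chi <- sum((tab - 100)^2 / 100)
  expect_lt(chi, qchisq(0.999, 5))
  # and consequently the two null means coincide on the star, so the raw
  # change scores of the two nulls agree in distribution
  star24 <- ape::read.tree(text = paste0(
    "(", paste0("t", 1:24, ":1", collapse = ","), ");"))
  st <- sim_threshold_trait(star24, 12, seed = 99)
  nr <- d_null_distribution(star24, st, "shuffle", n = 400, seed = 1)
  nb <- d_null_distribution(star24, st, "brownian", n = 400, seed = 2)
  expect_equal(mean(nr), mean(nb), tolerance = 0.02)
})

test_that("autologistic generator is seeded and respects the independence limit", {
  meta <- sim_metadata(n = 24, n_subfamilies = 4, seed = 2)
  gp <- build_phylo_graph(meta)
  gs <- build_spatial_graph(meta, 1500)
  m0 <- sim_autologistic_traits(gp, gs, 0, 0, 0, n_traits = 40, seed = 5,
                                burnin_sweeps = 200)
  expect_equal(mean(unclass(m0)), 0.5, tolerance = 0.05)
  expect_identical(unclass(sim_autologistic_traits(gp, gs, -1, 1, 0.5, 3, seed = 6)),
                   unclass(sim_autologistic_traits(gp, gs, -1, 1, 0.5, 3, seed = 6)))
})

test_that("strong phylogenetic coupling clusters traits within subfamilies", {
  meta <- sim_metadata(n = 24, n_subfamilies = 4, seed = 2)
  gp <- build_phylo_graph(meta)
  gs <- build_spatial_graph(meta, 1500)
  m <- sim_autologistic_traits(gp, gs, 0, 2.5, 0, n_traits = 60, seed = 7,
                               burnin_sweeps = 3000, weights = "scaled")
  X <- unclass(m)
  sf <- meta$subfamily[match(rownames(X), meta$society)]
  same_sf <- outer(sf, sf, "==")
  concord <- function(i, j) mean(X[i, ] == X[j, ])
  within <- c(); between <- c()
  for (i in 1:(nrow(X) - 1)) for (j in (i + 1):nrow(X)) {
    if (same_sf[i, j]) within <- c(within, concord(i, j))
    else between <- c(between, concord(i, j))
  }
  expect_gt(mean(within), mean(between))
})

test_that("metadata generator produces valid, partially overlapping structure", {
  meta <- sim_metadata(n = 50, n_subfamilies = 8, seed = 11)
  expect_s3_class(meta, "society_metadata")
  expect_true(all(abs(meta$lat) <= 90) && all(abs(meta$lon) <= 180))
  expect_equal(length(unique(meta$subfamily)), 8)
  # one subfamily: complete phylogenetic graph
  m1 <- sim_metadata(n = 8, n_subfamilies = 1, seed = 12)
  expect_equal(mean_degree(build_phylo_graph(m1)), 7)
  # tight clusters on a huge extent: spatial edges mostly mirror subfamilies
  tight <- sim_metadata(n = 30, n_subfamilies = 6, extent_km = 12000,
                        cluster_sd_km = 80, seed = 13)
  s <- graph_summary(build_phylo_graph(tight),
                     build_spatial_graph(tight, 600))
  expect_gt(s$shared, s$unique_b)
  expect_identical(sim_metadata(20, 4, seed = 9), sim_metadata(20, 4, seed = 9))
})
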