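test_that("newick and nexus parsing agree and validate taxon sets", {
  nwk <- write_lines_tmp("((A:1,B:1):1,C:2);", ".nwk")
  s1 <- read_tree_sample(nwk)
  expect_length(s1, 1)
  expect_equal(sort(s1[[1]]$tip.label), c("A", "B", "C"))
  expect_equal(ape::Ntip(s1[[1]]), 3)
  root_kids <- s1[[1]]$edge[s1[[1]]$edge[, 1] == 4, 2]
  expect_length(root_kids, 2)

  nex <- write_lines_tmp(c(
    "#NEXUS", "BEGIN TREES;",
    "  TRANSLATE", "    1 A,", "    2 B,", "    3 C", "  ;",
    "  TREE one = ((1:1,2:1):1,3:2);",
    "END;"), ".nex")
  s2 <- read_tree_sample(nex)
  expect_equal(ape::cophenetic.phylo(s2[[1]]), ape::cophenetic.phylo(s1[[1]]))

  # a multi-line newick file reports one tree per line
  n_lines <- 37
  multi <- write_lines_tmp(rep("((A:1,B:1):1,C:2);", n_lines), ".nwk")
  expect_length(read_tree_sample(multi), length(readLines(multi)))

  bad <- write_lines_tmp(c("((A:1,B:1):1,C:2);", "((A:1,B:1):1,D:2);"), ".nwk")
  expect_error(read_tree_sample(bad), "different taxon set")
  expect_error(read_tree_sample(write_lines_tmp("((A:1,B:1):1,C:2", ".nwk")))
})

test_that("round-trip write/read preserves topology, labels and lengths", {
  for (seed in 1:5) {
    tr <- random_tree(12, seed)
    f <- tempfile(fileext = ".nwk")
    write_tree_sample(tr, f)
    back <- read_tree_sample(f)[[1]]
    expect_equal(sort(back$tip.label), sort(tr$tip.label))
    expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
                 ape::cophenetic.phylo(tr), tolerance = 1e-9)
  }
})

test_that("prune_and_root keeps the outgroup and preserves path lengths", {
  tr <- balanced_quartet()
  p <- prune_and_root(tr, c("A", "B"), "C")
  expect_setequal(p$tip.label, c("A", "B", "C"))
  cp <- ape::cophenetic.phylo(p)
  expect_equal(cp["A", "C"], 4)   # 1 + 1 + 2 from the original tree
  expect_equal(cp["A", "B"], 2)

  # pruning keeps all pairwise path lengths among retained taxa
  big <- random_tree(20, 7)
  keep <- big$tip.label[c(2, 5, 9, 13, 17)]
  og <- big$tip.label[1]
  pr <- prune_and_root(big, keep, og)
  expect_setequal(pr$tip.label, c(keep, og))
  full <- ape::cophenetic.phylo(big)[c(keep, og), c(keep, og)]
  expect_equal(ape::cophenetic.phylo(pr)[c(keep, og), c(keep, og)], full,
               tolerance = 1e-9)

  # keeping everything is the identity up to representation
  all_t <- prune_and_root(big, big$tip.label, og)
  expect_equal(ape::cophenetic.phylo(all_t)[big$tip.label, big$tip.label],
               ape::cophenetic.phylo(big), tolerance = 1e-9)

  expect_error(prune_and_root(tr, character(0), "C"), "empty")
  expect_error(prune_and_root(tr, c("A", "B"), "Z"), "not in tree")
})

test_that("majority consensus keeps exactly the clades above threshold", {
  s1 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,O:3);")
  s2 <- ape::read.tree(text = "(((A:1,C:1):1,B:2):1,O:3);")

  # unanimity: consensus equals the tree, all frequencies 1
  smp <- c(s1, s1, s1)
  con <- majority_consensus(smp, 0.5, "O")
  expect_true(all(con$clades$frequency == 1))
  expect_equal(ape::cophenetic.phylo(con$tree), ape::cophenetic.phylo(s1))

  # 6:4 split: clade {A,B} retained at 0.6
  smp <- c(rep(c(s1), 6), rep(c(s2), 4))
  class(smp) <- "multiPhylo"
  con <- majority_consensus(smp, 0.5, "O")
  ab <- con$clades[con$clades$clade == "A;B", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$frequency, 0.6)
  expect_false("A;C" %in% con$clades$clade)

  # 50/50 conflict: neither clade clears a strict > 0.5 rule -> polytomy
  smp <- c(rep(c(s1), 5), rep(c(s2), 5))
  class(smp) <- "multiPhylo"
  con <- majority_consensus(smp, 0.5, "O")
  expect_false(any(c("A;B", "A;C") %in% con$clades$clade))
  ingroup_node <- con$clades$clade == "A;B;C"
  expect_true(any(ingroup_node))
  # root of the ingroup is a trichotomy
  n_desc <- table(con$tree$edge[, 1])
  expect_true(any(n_desc == 3))

  expect_error(majority_consensus(smp, 0.4, "O"), "0.5")
})

test_that("consensus clade frequencies exceed the threshold and are compatible", {
  set.seed(42)
  base <- random_tree(10, 42)
  og <- base$tip.label[1]
  reps <- lapply(1:30, function(i) {
    tr <- base
    tr$edge.length <- tr$edge.length * exp(rnorm(length(tr$edge.length), 0, 0.1))
    if (i %% 3 == 0) {
      labs <- sample(setdiff(tr$tip.label, og))
      tr$tip.label[match(labs, tr$tip.label)] <- labs[c(2:length(labs), 1)]
    }
    tr
  })
  class(reps) <- "multiPhylo"
  con <- majority_consensus(reps, 0.5, og)
  expect_true(all(con$clades$frequency > 0.5 & con$clades$frequency <= 1))
  # nesting compatibility: any two retained clades are disjoint or nested
  sets <- strsplit(con$clades$clade, ";", fixed = TRUE)
  for (a in seq_along(sets)) for (b in seq_len(a - 1)) {
    inter <- length(intersect(sets[[a]], sets[[b]]))
    expect_true(inter == 0 || inter == min(length(sets[[a]]), length(sets[[b]])))
  }
})

test_that("clade_frequency matches a brute-force per-tree monophyly check", {
  expect_equal(clade_frequency(c(balanced_quartet(), balanced_quartet()),
                               c("A", "B")), 1)
  set.seed(11)
  sim <- sim_tree_sample(n_taxa = 12, n_trees = 40, seed = 11,
                         root_nni_prob = 0.5)
  taxa <- sample(setdiff(sim$sample[[1]]$tip.label, sim$outgroup), 5)
  freq <- clade_frequency(sim$sample, taxa, sim$outgroup)
  brute <- mean(vapply(sim$sample, function(tr) {
    tr <- ape::root(tr, outgroup = sim$outgroup, resolve.root = TRUE)
    mrca <- ape::getMRCA(tr, taxa)
    desc <- ape::extract.clade(tr, mrca)$tip.label
    setequal(desc, taxa)
  }, logical(1)))
  expect_equal(freq, brute)
  # the full ingroup is always a clade on outgroup-rooted trees
  expect_equal(clade_frequency(sim$sample,
                               setdiff(sim$sample[[1]]$tip.label, sim$outgroup),
                               sim$outgroup), 1)
  expect_error(clade_frequency(sim$sample, "s01"), "at least 2")
})
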