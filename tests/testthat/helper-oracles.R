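# Independent oracles: brute-force enumeration implementations used to
# check the package's algorithms. These deliberately avoid the package's
# own traversal/likelihood code paths (transition probabilities come from
# a numerical matrix exponential, likelihoods from explicit sums over all
# internal-state assignments, autologistic laws from full 2^n enumeration).

# numerical matrix exponential of the 2-state rate matrix
oracle_pmat <- function(q01, q10, t) {
  Q <- matrix(c(-q01, q10, q01, -q10), 2, 2)
  as.matrix(Matrix::expm(Q * t))
}

# likelihood by summing over every assignment of states to free nodes
# (internal nodes and missing tips)
oracle_mk_loglik <- function(tree, states, q01, q10, root_prior = c(0.5, 0.5)) {
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  states <- states[tree$tip.label]
  free <- c(which(is.na(states)), seq.int(n + 1L, m))
  fixed <- setNames(as.integer(states[!is.na(states)]),
                    which(!is.na(states)))
  edges <- tree$edge
  lens <- tree$edge.length
  P <- lapply(seq_len(nrow(edges)), function(k) oracle_pmat(q01, q10, lens[k]))
  total <- 0
  for (code in 0:(2^length(free) - 1)) {
    assign <- integer(m)
    assign[as.integer(names(fixed))] <- fixed
    bits <- as.integer(intToBits(code))[seq_along(free)]
    assign[free] <- bits
    p <- root_prior[assign[n + 1L] + 1L]
    for (k in seq_len(nrow(edges)))
      p <- p * P[[k]][assign[edges[k, 1]] + 1L, assign[edges[k, 2]] + 1L]
    total <- total + p
  }
  log(total)
}

# marginal P(node = 1) by enumeration
oracle_mk_marginal <- function(tree, states, q01, q10, node,
                               root_prior = c(0.5, 0.5)) {
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  states <- states[tree$tip.label]
  free <- c(which(is.na(states)), seq.int(n + 1L, m))
  fixed <- setNames(as.integer(states[!is.na(states)]), which(!is.na(states)))
  edges <- tree$edge
  P <- lapply(seq_len(nrow(edges)),
              function(k) oracle_pmat(q01, q10, tree$edge.length[k]))
  tot <- c(0, 0)
  for (code in 0:(2^length(free) - 1)) {
    assign <- integer(m)
    assign[as.integer(names(fixed))] <- fixed
    assign[free] <- as.integer(intToBits(code))[seq_along(free)]
    p <- root_prior[assign[n + 1L] + 1L]
    for (k in seq_len(nrow(edges)))
      p <- p * P[[k]][assign[edges[k, 1]] + 1L, assign[edges[k, 2]] + 1L]
    tot[assign[node] + 1L] <- tot[assign[node] + 1L] + p
  }
  tot[2] / sum(tot)
}

# exact D-statistic p-value: enumerate every arrangement with the observed
# number of present tips
oracle_d_pvalue <- function(tree, states) {
  n <- ape::Ntip(tree)
  k <- sum(states == 1)
  d_obs <- nodal_changes(tree, states)
  combos <- utils::combn(n, k)
  d_all <- apply(combos, 2, function(idx) {
    s <- setNames(integer(n), tree$tip.label)
    s[idx] <- 1L
    nodal_changes(tree, s)
  })
  mean(d_all <= d_obs)
}

# edge list of a neighbor_graph as index pairs into `nodes`
oracle_edge_idx <- function(g, nodes) {
  if (!nrow(g$edges)) return(matrix(integer(0), 0, 2))
  cbind(match(g$edges[, 1], nodes), match(g$edges[, 2], nodes))
}

# exact autologistic distribution over all 2^n states; state `code` has
# node j present iff bit j-1 set (nodes in ascending label order), matching
# gibbs_state_census()
oracle_autologistic_dist <- function(g_phylo, g_spatial, beta, lambda, theta,
                                     wp = 1, ws = 1) {
  nodes <- sort(g_phylo$nodes)
  n <- length(nodes)
  ep <- oracle_edge_idx(g_phylo, nodes)
  es <- oracle_edge_idx(g_spatial, nodes)
  loge <- vapply(0:(2^n - 1), function(code) {
    x <- as.integer(intToBits(code))[seq_len(n)]
    beta * sum(x) +
      lambda * wp * (if (nrow(ep)) sum(x[ep[, 1]] * x[ep[, 2]]) else 0) +
      theta * ws * (if (nrow(es)) sum(x[es[, 1]] * x[es[, 2]]) else 0)
  }, numeric(1))
  w <- exp(loge - max(loge))
  w / sum(w)
}

# exact maximum likelihood for the autologistic model on a small graph
oracle_autologistic_mle <- function(x, g_phylo, g_spatial, wp = 1, ws = 1) {
  nodes <- sort(g_phylo$nodes)
  x <- x[nodes]
  n <- length(nodes)
  ep <- oracle_edge_idx(g_phylo, nodes)
  es <- oracle_edge_idx(g_spatial, nodes)
  stat <- function(x) c(sum(x),
                        wp * (if (nrow(ep)) sum(x[ep[, 1]] * x[ep[, 2]]) else 0),
                        ws * (if (nrow(es)) sum(x[es[, 1]] * x[es[, 2]]) else 0))
  S_all <- t(vapply(0:(2^n - 1), function(code)
    stat(as.integer(intToBits(code))[seq_len(n)]), numeric(3)))
  s_obs <- stat(as.integer(x))
  nll <- function(th) {
    e <- S_all %*% th
    -(sum(th * s_obs) - (max(e) + log(sum(exp(e - max(e))))))
  }
  optim(c(0, 0, 0), nll, method = "BFGS")$par
}

# quick fixtures -----------------------------------------------------------

balanced_quartet <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rphylo(n, 1, 0)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# small dual graphs on n nodes: ring (phylo) + chord graph (spatial)
toy_dual_graphs <- function(n) {
  nodes <- sprintf("n%02d", seq_len(n))
  ring <- cbind(nodes, nodes[c(2:n, 1)])
  chords <- cbind(nodes[seq_len(n - 2)], nodes[seq.int(3, n)])
  list(phylo = folkphylo:::new_neighbor_graph(nodes, ring, "phylogenetic"),
       spatial = folkphylo:::new_neighbor_graph(nodes, chords, "spatial"))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
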