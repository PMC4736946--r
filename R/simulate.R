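#' Simulate a posterior-like sample of rooted trees
#'
#' Generates one pure-birth "true" ingroup tree with an outgroup attached
#' below the ingroup root, then perturbed replicates: with probability
#' `root_nni_prob` a nearest-neighbour interchange is applied at an edge
#' adjacent to the ingroup root (so topological uncertainty concentrates
#' in the deepest clades, as in empirical posteriors where deep-clade
#' frequencies fall into roughly [0.7, 1.0]), and every branch length is
#' jittered log-normally.
#'
#' @param n_taxa total tips including the outgroup (>= 4).
#' @param n_trees replicates in the sample.
#' @param seed optional integer seed.
#' @param root_nni_prob probability a replicate receives one root-adjacent
#'   NNI move.
#' @param jitter_sd standard deviation of the log-normal branch jitter.
#' @param outgroup outgroup tip label.
#' @return list: `sample` (a `multiPhylo` of `n_trees` trees), `true_tree`,
#'   `outgroup`.
#' @export
sim_tree_sample <- function(n_taxa = 50, n_trees = 1000, seed = NULL,
                            root_nni_prob = 0.25, jitter_sd = 0.05,
                            outgroup = "outgroup") {
  if (n_taxa < 4) stop("need at least 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  ingroup <- ape::rphylo(n_taxa - 1L, birth = 1, death = 0)
  ingroup$tip.label <- sprintf("s%02d", seq_len(n_taxa - 1L))
  depth <- max(ape::node.depth.edgelength(ingroup))
  og_len <- 1.2 * depth
  base <- ape::read.tree(text = sprintf("(ingroup:%g,%s:%g);", 0.2 * depth,
                                        outgroup, og_len))
  true_tree <- ape::bind.tree(base, ingroup, where = which(base$tip.label == "ingroup"))
  true_tree <- ape::reorder.phylo(true_tree, "cladewise")
  reps <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    tr <- true_tree
    if (runif(1) < root_nni_prob) tr <- root_nni(tr)
    tr$edge.length <- tr$edge.length * exp(rnorm(length(tr$edge.length), 0, jitter_sd))
    reps[[i]] <- tr
  }
  class(reps) <- "multiPhylo"
  validate_tree_sample(reps)
  list(sample = reps, true_tree = true_tree, outgroup = outgroup)
}

# one NNI at an internal edge adjacent to the ingroup root: swap a child
# subtree of the chosen node with its sibling subtree
root_nni <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  root_kids <- tree$edge[tree$edge[, 1] == root, 2]
  ingroup_root <- root_kids[root_kids > n][1]
  if (is.na(ingroup_root)) return(tree)
  kids <- tree$edge[tree$edge[, 1] == ingroup_root, 2]
  internal_kids <- kids[kids > n]
  if (!length(internal_kids)) return(tree)
  c_node <- if (length(internal_kids) == 1) internal_kids
            else sample(internal_kids, 1)
  sib <- setdiff(kids, c_node)
  if (!length(sib)) return(tree)
  s_node <- if (length(sib) == 1) sib else sample(sib, 1)
  grand <- tree$edge[tree$edge[, 1] == c_node, 2]
  d_node <- if (length(grand) == 1) grand else sample(grand, 1)
  e_s <- which(tree$edge[, 2] == s_node)
  e_d <- which(tree$edge[, 2] == d_node)
  tree$edge[e_s, 1] <- c_node
  tree$edge[e_d, 1] <- ingroup_root
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate binary traits under the Mk model
#'
#' The root state is drawn from the stationary distribution and states
#' evolve edge by edge under the 2-state chain's transition probabilities.
#' True internal-node states are recorded as ground truth for
#' reconstruction benchmarks.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param q01,q10 gain and loss rates (>= 0).
#' @param n_traits number of independent traits.
#' @param seed optional integer seed.
#' @return list: `matrix` (a `trait_matrix`, taxa x traits) and
#'   `node_states` (internal-node truth, nodes x traits).
#' @export
sim_mk_traits <- function(tree, q01, q10, n_traits = 1, seed = NULL) {
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  info <- postorder_info(tree)
  r <- q01 + q10
  pi1 <- if (r == 0) 0.5 else q01 / r
  states <- matrix(NA_integer_, info$n_node, n_traits)
  states[info$root, ] <- rbinom(n_traits, 1, pi1)
  e <- exp(-r * info$edge_len)
  for (k in seq_len(nrow(info$pre_edges))) {
    par <- info$pre_edges[k, 1]; ch <- info$pre_edges[k, 2]
    ech <- if (is.na(e[ch])) 1 else e[ch]
    p1 <- ifelse(states[par, ] == 1, pi1 + (1 - pi1) * ech, pi1 * (1 - ech))
    states[ch, ] <- rbinom(n_traits, 1, p1)
  }
  tips <- states[seq_len(info$n_tip), , drop = FALSE]
  dimnames(tips) <- list(info$tip_labels, sprintf("trait_%03d", seq_len(n_traits)))
  internal <- states[seq.int(info$n_tip + 1L, info$n_node), , drop = FALSE]
  rownames(internal) <- as.character(seq.int(info$n_tip + 1L, info$n_node))
  list(matrix = trait_matrix(tips), node_states = internal)
}

#' Simulate a threshold-Brownian binary trait
#'
#' Brownian motion along the branches from a root value of 0; the tip
#' values are cut by rank so that exactly `k_present` tips are present.
#' This is the purely vertical reference process for which the D statistic
#' is calibrated to 0.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param k_present number of present tips (1 to tips - 1).
#' @param seed optional integer seed.
#' @return named binary vector over tips.
#' @export
sim_threshold_trait <- function(tree, k_present, seed = NULL) {
  n <- ape::Ntip(tree)
  if (k_present < 1 || k_present > n - 1)
    stop("k_present must be in [1, n_tips - 1]")
  if (!is.null(seed)) set.seed(seed)
  info <- postorder_info(tree)
  x <- drop(brownian_tip_values(info, 1))
  out <- setNames(integer(n), info$tip_labels)
  out[order(x, decreasing = TRUE)[seq_len(k_present)]] <- 1L
  out
}

#' Simulate traits from the autologistic model
#'
#' Each trait is the end state of an independent long-run Gibbs chain at
#' the given parameters, i.e. an (approximate) draw from the autologistic
#' joint distribution on the dual graphs.
#'
#' @param g_phylo,g_spatial `neighbor_graph`s on the same societies.
#' @param beta,lambda,theta model parameters.
#' @param n_traits number of independent fields.
#' @param seed optional integer seed.
#' @param burnin_sweeps sweeps before the recorded state (>= 1e4 by
#'   default so chains forget their random initialisation).
#' @param weights `"sum"` or `"scaled"` neighbour terms.
#' @return a `trait_matrix` (societies x traits).
#' @export
sim_autologistic_traits <- function(g_phylo, g_spatial, beta, lambda, theta,
                                    n_traits = 1, seed = NULL,
                                    burnin_sweeps = 10000, weights = "sum") {
  if (!is.null(seed)) set.seed(seed)
  params <- autologistic_params(beta, lambda, theta)
  cols <- lapply(seq_len(n_traits), function(j) {
    drop(gibbs_field(g_phylo, g_spatial, params,
                     sweeps = burnin_sweeps + 1, thin = 1,
                     burnin = burnin_sweeps, weights = weights))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- sprintf("trait_%03d", seq_len(n_traits))
  trait_matrix(m)
}

#' Simulate society metadata
#'
#' Societies are assigned to subfamilies whose centroids are scattered over
#' a continental-scale extent; members cluster around their centroid so
#' the spatial and phylogenetic neighbour graphs overlap partially, as in
#' real language families where relatives tend to be (but are not always)
#' geographic neighbours.
#'
#' @param n societies.
#' @param n_subfamilies subfamily groups (<= n).
#' @param extent_km approximate east-west span of the region.
#' @param seed optional integer seed.
#' @param cluster_sd_km spread of societies around their subfamily centroid.
#' @param center_lat,center_lon centre of the region (default Eurasian).
#' @return a `society_metadata` data frame with societies `s01, s02, ...`.
#' @export
sim_metadata <- function(n = 50, n_subfamilies = 8, extent_km = 6000,
                         seed = NULL, cluster_sd_km = 400,
                         center_lat = 45, center_lon = 40) {
  if (n < n_subfamilies) stop("n must be >= n_subfamilies")
  if (!is.null(seed)) set.seed(seed)
  km_per_deg <- 6371 * pi / 180
  half_deg <- extent_km / 2 / km_per_deg
  cen_lon <- center_lon + runif(n_subfamilies, -half_deg, half_deg)
  cen_lat <- center_lat + runif(n_subfamilies, -half_deg / 2, half_deg / 2)
  sf <- sort(rep_len(seq_len(n_subfamilies), n))
  sd_deg <- cluster_sd_km / km_per_deg
  lat <- pmin(pmax(cen_lat[sf] + rnorm(n, 0, sd_deg), -89), 89)
  lon <- ((cen_lon[sf] + rnorm(n, 0, sd_deg) + 180) %% 360) - 180
  society_metadata(data.frame(
    society = sprintf("s%02d", seq_len(n)), lat = lat, lon = lon,
    subfamily = sprintf("sf%d", sf), point_id = seq_len(n),
    stringsAsFactors = FALSE))
}
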