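#' Sum of sister-clade differences for a binary trait
#'
#' The raw change score underlying the D statistic. Tip values are passed
#' up the tree: each internal node takes the mean of its children's values
#' (polytomies average over all children), and the score is the sum over
#' internal nodes of the absolute differences between each child's value
#' and the node's value. It is 0 iff all tips share one state, and grows
#' with the number of state changes the trait implies on the tree.
#'
#' @param tree a rooted `phylo` object.
#' @param states per-tip values in `[0, 1]`, named by tip label (or in tip
#'   order). Missing values are not allowed here; drop those tips first.
#' @return a non-negative scalar.
#' @export
nodal_changes <- function(tree, states) {
  s <- match_tip_states(tree, states, mode = "double")
  drop(nodal_changes_matrix(postorder_info(tree), matrix(s, ncol = 1)))
}

# vectorised core: S is an n_tip x m matrix of tip values (tip order);
# returns length-m vector of change scores
nodal_changes_matrix <- function(info, S) {
  m <- ncol(S)
  vals <- matrix(0, info$n_node, m)
  vals[seq_len(info$n_tip), ] <- S
  d <- numeric(m)
  for (v in info$post_nodes) {
    ch <- info$children[[v]]
    block <- vals[ch, , drop = FALSE]
    nodeval <- colMeans(block)
    vals[v, ] <- nodeval
    d <- d + colSums(abs(sweep(block, 2, nodeval, "-")))
  }
  d
}

# Brownian tip values: for each of m simulations, tip value = sum of
# N(0, branch length) increments from root (value 0) to tip
brownian_tip_values <- function(info, m) {
  vals <- matrix(0, info$n_node, m)
  E <- info$pre_edges
  sdlen <- sqrt(pmax(info$edge_len, 0))
  for (k in seq_len(nrow(E))) {
    ch <- E[k, 2]
    vals[ch, ] <- vals[E[k, 1], ] + rnorm(m, 0, sdlen[ch])
  }
  vals[seq_len(info$n_tip), , drop = FALSE]
}

# threshold a matrix of continuous tip values so each column has exactly k ones
rank_threshold <- function(X, k) {
  apply(X, 2, function(x) {
    out <- integer(length(x))
    out[order(x, decreasing = TRUE)[seq_len(k)]] <- 1L
    out
  })
}

#' Null distributions of the change score
#'
#' Two nulls calibrate the D statistic: `"shuffle"` permutes the observed
#' tip states uniformly (phylogenetically random arrangement, D = 1 on
#' average), and `"brownian"` simulates Brownian motion along the branches
#' from a root value of 0 and thresholds the tip values by rank so that
#' exactly the observed number of tips are present (the purely vertical,
#' neutral reference, D = 0 on average).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param states binary tip states named by tip label, no missing values.
#' @param kind `"shuffle"` or `"brownian"`.
#' @param n number of simulated traits.
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of `n` change scores.
#' @export
d_null_distribution <- function(tree, states, kind = c("shuffle", "brownian"),
                                n = 1000, seed = NULL) {
  kind <- match.arg(kind)
  if (n < 1) stop("n must be >= 1")
  s <- match_tip_states(tree, states)
  if (length(unique(s)) < 2L) stop("constant trait: null distribution undefined")
  if (!is.null(seed)) set.seed(seed)
  info <- postorder_info(tree)
  k <- sum(s == 1L)
  S <- if (kind == "shuffle") {
    replicate(n, sample(as.numeric(s)))
  } else {
    rank_threshold(brownian_tip_values(info, n), k)
  }
  nodal_changes_matrix(info, S)
}

#' Fritz-Purvis D for one binary trait
#'
#' Computes the observed change score, scales it between the means of the
#' tip-shuffle and threshold-Brownian null distributions,
#' `D = (d_obs - mean(brownian)) / (mean(shuffle) - mean(brownian))`,
#' and reports one-tailed p-values for phylogenetic clumping: the fraction
#' of null scores less than or equal to the observed score. Tips with a
#' missing state are dropped from the trait's copy of the tree. Constant
#' traits are flagged and returned with `D = NA`.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param states binary tip states (0/1/NA) named by tip label.
#' @param n_sims simulations per null distribution.
#' @param seed optional integer seed.
#' @param trait optional trait id carried into the result.
#' @return an object of class `d_result`: list with `trait`, `d_obs`, `D`,
#'   `p_random`, `p_brownian`, `null_random`, `null_brownian`, `n_sims`,
#'   `n_tips`, `prevalence`, `constant`, `seed`.
#' @export
compute_d <- function(tree, states, n_sims = 1000, seed = NULL, trait = NA_character_) {
  s <- match_tip_states(tree, states, allow_missing = TRUE)
  if (anyNA(s)) {
    keep <- names(s)[!is.na(s)]
    if (length(keep) < 3L) stop("fewer than 3 scored tips")
    tree <- ape::keep.tip(tree, keep)
    s <- s[keep]
  }
  res <- list(trait = trait, n_tips = length(s),
              prevalence = mean(s == 1L), n_sims = n_sims, seed = seed)
  if (length(unique(s)) < 2L) {
    res <- c(res, list(d_obs = 0, D = NA_real_, p_random = NA_real_,
                       p_brownian = NA_real_, null_random = NULL,
                       null_brownian = NULL, constant = TRUE))
    return(structure(res, class = "d_result"))
  }
  if (!is.null(seed)) set.seed(seed)
  info <- postorder_info(tree)
  d_obs <- drop(nodal_changes_matrix(info, matrix(as.numeric(s), ncol = 1)))
  null_r <- nodal_changes_matrix(info, replicate(n_sims, sample(as.numeric(s))))
  null_b <- nodal_changes_matrix(
    info, rank_threshold(brownian_tip_values(info, n_sims), sum(s == 1L)))
  D <- (d_obs - mean(null_b)) / (mean(null_r) - mean(null_b))
  res <- c(res, list(d_obs = d_obs, D = D,
                     p_random = mean(null_r <= d_obs),
                     p_brownian = mean(null_b <= d_obs),
                     null_random = null_r, null_brownian = null_b,
                     constant = FALSE))
  structure(res, class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  if (x$constant) {
    cat("D result", if (!is.na(x$trait)) paste0("for ", x$trait),
        ": constant trait, D undefined\n")
  } else {
    cat(sprintf("D result%s: d_obs = %.3f, D = %.3f, p(random) = %.4f, p(brownian) = %.4f [%d sims, %d tips]\n",
                if (!is.na(x$trait)) paste0(" for ", x$trait) else "",
                x$d_obs, x$D, x$p_random, x$p_brownian, x$n_sims, x$n_tips))
  }
  invisible(x)
}

#' Screen every trait of a matrix for phylogenetic signal
#'
#' Runs [compute_d()] per trait on the given tree (typically the
#' majority-rules consensus) and flags traits whose tip-shuffle p-value
#' falls below `alpha` — i.e. traits significantly more phylogenetically
#' clumped than a random arrangement. Constant traits are excluded from
#' screening (significant = `NA`).
#'
#' @param tree a rooted `phylo` (or a `consensus_tree`, whose tree is used).
#' @param m a `trait_matrix`; taxa absent from the tree are ignored, tree
#'   tips absent from the matrix are treated as missing and dropped.
#' @param n_sims simulations per null per trait.
#' @param alpha significance level for the clumping test.
#' @param seed optional integer seed (per-trait seeds are derived from it).
#' @return data frame, one row per trait: trait, n_tips, prevalence, d_obs,
#'   D, p_random, p_brownian, constant, significant.
#' @export
d_screen <- function(tree, m, n_sims = 1000, alpha = 0.05, seed = NULL) {
  if (inherits(tree, "consensus_tree")) tree <- tree$tree
  if (!is.null(seed)) set.seed(seed)
  trait_seeds <- sample.int(.Machine$integer.max, ncol(m))
  rows <- lapply(seq_len(ncol(m)), function(j) {
    states <- setNames(unclass(m)[, j], rownames(m))
    states <- states[names(states) %in% tree$tip.label]
    miss_tips <- setdiff(tree$tip.label, names(states))
    if (length(miss_tips))
      states <- c(states, setNames(rep(NA_integer_, length(miss_tips)), miss_tips))
    r <- compute_d(tree, states, n_sims = n_sims, seed = trait_seeds[j],
                   trait = colnames(m)[j])
    data.frame(trait = r$trait, n_tips = r$n_tips, prevalence = r$prevalence,
               d_obs = r$d_obs, D = r$D, p_random = r$p_random,
               p_brownian = r$p_brownian, constant = r$constant,
               significant = if (r$constant) NA else r$p_random < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}

#' Outgroup-coding sensitivity of the signal screen
#'
#' The screening stage cannot use missing data, so an outgroup without
#' trait records must be coded all-absent or all-present. This harness
#' reruns the screen under both codings and reports the set differences of
#' significant traits, to check that conclusions do not hinge on the
#' arbitrary choice.
#'
#' @param tree rooted `phylo` or `consensus_tree` including the outgroup.
#' @param m a `trait_matrix` (without or with the outgroup row).
#' @param outgroup outgroup taxon label.
#' @inheritParams d_screen
#' @return list with both screen tables (`absent`, `present`), the traits
#'   significant under only one coding (`only_absent`, `only_present`) and
#'   the stable significant set (`both`).
#' @export
outgroup_sensitivity <- function(tree, m, outgroup, n_sims = 1000,
                                 alpha = 0.05, seed = NULL) {
  scr <- lapply(c("absent", "present"), function(pol) {
    d_screen(tree, set_outgroup_state(m, outgroup, pol),
             n_sims = n_sims, alpha = alpha, seed = seed)
  })
  sig <- lapply(scr, function(s) s$trait[!is.na(s$significant) & s$significant])
  list(absent = scr[[1]], present = scr[[2]],
       only_absent = setdiff(sig[[1]], sig[[2]]),
       only_present = setdiff(sig[[2]], sig[[1]]),
       both = intersect(sig[[1]], sig[[2]]))
}
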