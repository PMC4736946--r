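#' Control settings for the Bayesian ancestral-state machinery
#'
#' @param iters MCMC iterations (study-scale default one million).
#' @param thin sampling interval (study-scale default every 1000th).
#' @param burnin_frac fraction of iterations discarded as burn-in.
#' @param tree_move_prob probability of proposing a new tree index (vs a
#'   rate move) at each iteration.
#' @param prior_mult uniform rate priors run from 0 to `prior_mult` times
#'   the maximum-likelihood rate estimate (the empirical-range rule).
#' @param rungs number of stepping-stone power-posterior rungs.
#' @param rung_iters iterations per rung (default `iters / rungs`).
#' @param ss_alpha rung powers follow `(k/rungs)^(1/ss_alpha)`; 0.3
#'   concentrates rungs near the prior where the integrand varies most.
#' @param ml_method `"stepping_stone"` (default) or `"harmonic"` marginal
#'   likelihood estimator. The harmonic-mean estimator is retained only for
#'   comparison with legacy analyses; it is notoriously unstable.
#' @return list of class `bayes_control`.
#' @export
bayes_control <- function(iters = 1e6, thin = 1000, burnin_frac = 0.1,
                          tree_move_prob = 0.3, prior_mult = 10,
                          rungs = 10, rung_iters = NULL, ss_alpha = 0.3,
                          ml_method = c("stepping_stone", "harmonic")) {
  structure(list(iters = as.integer(iters), thin = as.integer(thin),
                 burnin_frac = burnin_frac, tree_move_prob = tree_move_prob,
                 prior_mult = prior_mult, rungs = rungs,
                 rung_iters = rung_iters %||% max(500L, as.integer(iters / rungs)),
                 ss_alpha = ss_alpha, ml_method = match.arg(ml_method)),
            class = "bayes_control")
}

#' Empirical uniform prior range for transition rates
#'
#' Uniform `[0, upper]` priors with `upper = mult` times the largest
#' maximum-likelihood rate across a few trees of the sample.
#'
#' @param sample a `multiPhylo` tree sample.
#' @param states tip states named by label.
#' @param mult multiple of the ML estimate.
#' @param n_trees how many (evenly spaced) trees to fit.
#' @return list with `q01 = c(0, upper)` and `q10 = c(0, upper)`.
#' @export
empirical_rate_prior <- function(sample, states, mult = 10, n_trees = 3) {
  idx <- unique(round(seq(1, length(sample), length.out = min(n_trees, length(sample)))))
  rates <- vapply(idx, function(i) {
    m <- fit_mk(sample[[i]], states, "Mk2")
    max(m$q01, m$q10)
  }, numeric(1))
  upper <- max(mult * max(rates), 1e-3)
  list(q01 = c(0, upper), q10 = c(0, upper))
}

# cached pruning context for each tree of a sample
bayes_cache <- function(sample, states, fix_taxa = NULL) {
  lapply(sample, function(tr) {
    s <- match_tip_states(tr, states, allow_missing = TRUE)
    fix_node <- NULL
    if (!is.null(fix_taxa)) {
      fix_node <- if (length(fix_taxa) >= ape::Ntip(tr)) info_root(tr)
                  else ape::getMRCA(tr, fix_taxa)
    }
    list(info = postorder_info(tr), tipL = tip_partials(s), fix_node = fix_node)
  })
}

cache_loglik <- function(cache_i, q01, q10, root_prior, fix_state = NULL) {
  pp <- prune_pass(cache_i$info, cache_i$tipL, q01, q10,
                   fix_node = if (is.null(fix_state)) NULL else cache_i$fix_node,
                   fix_state = fix_state)
  prior <- mk_root_prior(list(q01 = q01, q10 = q10), root_prior)
  lik <- sum(prior * pp$L[cache_i$info$root, ])
  if (lik <= 0 || !is.finite(pp$logscale[cache_i$info$root])) -Inf
  else log(lik) + pp$logscale[cache_i$info$root]
}

run_chain <- function(cache, prior, iters, thin, burnin, tree_move_prob,
                      root_prior, fix_state = NULL, power = 1,
                      state = NULL, window = NULL) {
  n_tr <- length(cache)
  up1 <- prior$q01[2]; up0 <- prior$q10[2]
  if (is.null(state)) {
    state <- list(k = sample.int(n_tr, 1),
                  q01 = runif(1, prior$q01[1], up1),
                  q10 = runif(1, prior$q10[1], up0))
    state$ll <- cache_loglik(cache[[state$k]], state$q01, state$q10,
                             root_prior, fix_state)
  }
  if (is.null(window)) window <- c(up1, up0) / 10
  reflect <- function(v, lo, hi) {
    # closed-form fold into [lo, hi] (robust to windows wider than the range)
    R <- hi - lo
    if (R <= 0) return(lo)
    y <- (v - lo) %% (2 * R)
    lo + ifelse(y > R, 2 * R - y, y)
  }
  keep <- floor((iters - burnin) / thin)
  draws <- matrix(NA_real_, keep, 4,
                  dimnames = list(NULL, c("tree", "q01", "q10", "loglik")))
  row <- 0L
  acc <- c(rate = 0, rate_n = 0, tree = 0, tree_n = 0)
  tune_acc <- 0; tune_n <- 0
  for (t in seq_len(iters)) {
    if (n_tr > 1 && runif(1) < tree_move_prob) {
      k2 <- sample.int(n_tr, 1)
      ll2 <- cache_loglik(cache[[k2]], state$q01, state$q10, root_prior, fix_state)
      if (log(runif(1)) < power * (ll2 - state$ll)) {
        state$k <- k2; state$ll <- ll2
        if (t > burnin) acc["tree"] <- acc["tree"] + 1
      }
      if (t > burnin) acc["tree_n"] <- acc["tree_n"] + 1
    } else {
      which_rate <- sample(1:2, 1)
      q01 <- state$q01; q10 <- state$q10
      if (which_rate == 1) q01 <- reflect(q01 + runif(1, -window[1], window[1]),
                                          prior$q01[1], up1)
      else q10 <- reflect(q10 + runif(1, -window[2], window[2]),
                          prior$q10[1], up0)
      ll2 <- cache_loglik(cache[[state$k]], q01, q10, root_prior, fix_state)
      accept <- log(runif(1)) < power * (ll2 - state$ll)
      if (accept) { state$q01 <- q01; state$q10 <- q10; state$ll <- ll2 }
      tune_n <- tune_n + 1; tune_acc <- tune_acc + accept
      if (t > burnin) {
        acc["rate_n"] <- acc["rate_n"] + 1
        acc["rate"] <- acc["rate"] + accept
      }
      # auto-tune the sliding window toward ~30% acceptance during burn-in
      if (t <= burnin && tune_n >= 100) {
        window <- pmin(pmax(window * exp(tune_acc / tune_n - 0.3),
                            c(up1, up0) * 1e-4), c(up1, up0))
        tune_acc <- 0; tune_n <- 0
      }
    }
    if (t > burnin && (t - burnin) %% thin == 0 && row < keep) {
      row <- row + 1L
      draws[row, ] <- c(state$k, state$q01, state$q10, state$ll)
    }
  }
  list(draws = as.data.frame(draws[seq_len(row), , drop = FALSE]),
       acceptance = c(rate = unname(acc["rate"] / max(acc["rate_n"], 1)),
                      tree = unname(acc["tree"] / max(acc["tree_n"], 1))),
       window = window, state = state)
}

#' Bayesian MCMC over trees and transition rates
#'
#' Metropolis-within-Gibbs sampler whose state is (tree index, gain rate,
#' loss rate): tree indices are proposed uniformly over the posterior tree
#' sample, rates by sliding-window proposals (reflected at the uniform
#' prior bounds, window auto-tuned during burn-in), and moves are accepted
#' by the likelihood ratio. Trees and rates are thereby sampled in
#' proportion to their posterior probabilities.
#'
#' @param sample a `multiPhylo` tree sample.
#' @param states binary/missing tip states named by tip label.
#' @param prior uniform prior ranges, as from [empirical_rate_prior()];
#'   `NULL` applies the empirical rule.
#' @param config a [bayes_control()] list (`iters`, `thin`, burn-in, moves).
#' @param seed optional integer seed.
#' @param root_prior `"equal"` or `"stationary"`.
#' @return list of class `multistate_mcmc`: `draws` (data frame: tree,
#'   q01, q10, loglik), `acceptance`, `window`, `prior`, `config`, `seed`.
#' @export
mcmc_multistate <- function(sample, states, prior = NULL,
                            config = bayes_control(), seed = NULL,
                            root_prior = "equal") {
  validate_tree_sample(sample)
  if (!is.null(seed)) set.seed(seed)
  prior <- prior %||% empirical_rate_prior(sample, states, config$prior_mult)
  if (any(c(prior$q01, prior$q10) < 0) || any(!is.finite(c(prior$q01, prior$q10))))
    stop("prior ranges must be non-negative and finite")
  cache <- bayes_cache(sample, states)
  burnin <- floor(config$iters * config$burnin_frac)
  res <- run_chain(cache, prior, config$iters, config$thin, burnin,
                   config$tree_move_prob, root_prior)
  if (res$acceptance[["rate"]] == 0 && nrow(res$draws) > 1)
    warning("zero acceptance of rate moves after tuning; check prior ranges")
  structure(list(draws = res$draws, acceptance = res$acceptance,
                 window = res$window, prior = prior, config = config,
                 seed = seed, root_prior = root_prior),
            class = "multistate_mcmc")
}

#' Posterior state probability at the MRCA of a taxon set
#'
#' For each posterior draw, locates the most recent common ancestor of the
#' taxa in that draw's tree (the smallest clade containing them, whether or
#' not they are monophyletic there), computes the marginal probability of
#' the trait being present at that node under the drawn rates, and averages
#' over draws.
#'
#' @param mcmc a [mcmc_multistate()] result (or its `draws` data frame).
#' @param sample the tree sample the chain indexed.
#' @param states tip states used in the chain.
#' @param taxa two or more tip labels defining the ancestor.
#' @param root_prior `"equal"` or `"stationary"`.
#' @return named numeric `c(p_present, p_absent)`.
#' @export
mrca_state_posterior <- function(mcmc, sample, states, taxa,
                                 root_prior = "equal") {
  draws <- if (is.data.frame(mcmc)) mcmc else mcmc$draws
  if (length(unique(taxa)) < 2L) stop("need at least 2 taxa")
  missing <- setdiff(taxa, sample[[1]]$tip.label)
  if (length(missing)) stop("taxa not in sample: ", paste(missing, collapse = ", "))
  p <- numeric(nrow(draws))
  for (g in split(seq_len(nrow(draws)), draws$tree)) {
    k <- draws$tree[g[1]]
    tr <- sample[[k]]
    node <- if (length(unique(taxa)) >= ape::Ntip(tr)) info_root(tr)
            else ape::getMRCA(tr, unique(taxa))
    for (j in g) {
      probs <- marginal_node_probs(tr, states,
                                   mk_model(draws$q01[j], draws$q10[j], "Mk2"),
                                   root_prior = root_prior)
      p[j] <- probs[[as.character(node)]]
    }
  }
  c(p_present = mean(p), p_absent = 1 - mean(p))
}

#' Stepping-stone log marginal likelihood
#'
#' Power-posterior path sampling from prior to posterior: rung `k` targets
#' `prior x likelihood^beta_k` with `beta_k = (k/K)^(1/alpha)`, and the log
#' marginal likelihood is the sum over rungs of the log mean importance
#' ratio `likelihood^(beta_{k+1} - beta_k)`. An optional node fix
#' (fossilisation) is applied inside the likelihood.
#'
#' @inheritParams mcmc_multistate
#' @param fix_taxa taxon set whose MRCA is fossilised (`NULL` = none).
#' @param fix_state 0 or 1, the fossilised state.
#' @return list: `logML`, per-rung contributions, `betas`.
#' @export
stepping_stone <- function(sample, states, prior, config = bayes_control(),
                           fix_taxa = NULL, fix_state = NULL,
                           root_prior = "equal", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cache <- bayes_cache(sample, states, fix_taxa)
  K <- config$rungs
  betas <- (seq(0, K) / K)^(1 / config$ss_alpha)
  iters <- config$rung_iters
  burnin <- floor(iters * config$burnin_frac)
  thin <- max(1L, as.integer(config$thin / K))
  contrib <- numeric(K)
  state <- NULL; window <- NULL
  for (k in seq_len(K)) {
    res <- run_chain(cache, prior, iters, thin, burnin, config$tree_move_prob,
                     root_prior, fix_state = fix_state, power = betas[k],
                     state = state, window = window)
    state <- res$state; window <- res$window
    contrib[k] <- log_mean_exp((betas[k + 1] - betas[k]) * res$draws$loglik)
  }
  list(logML = sum(contrib), contributions = contrib, betas = betas)
}

harmonic_logml <- function(draws) -log_mean_exp(-draws$loglik)

#' Kass-Raftery label for a Bayes factor
#'
#' On the `2 ln BF` scale: below 2 "weak", 2 to below 6 "positive", 6 to 10
#' "strong", above 10 "very strong".
#'
#' @param bf Bayes factor(s) on the `2 ln` scale.
#' @return character vector of labels.
#' @export
bayes_factor_label <- function(bf) {
  cut(bf, breaks = c(-Inf, 2, 6, 10 + 1e-12, Inf), right = FALSE,
      labels = c("weak", "positive", "strong", "very strong")) |>
    as.character()
}

#' Fossil test for the state of an ancestral node
#'
#' Fixes ("fossilises") the MRCA of `taxa` in each sampled tree first as
#' present and then as absent, estimates the log marginal likelihood of
#' each hypothesis (stepping-stone by default), and reports the Bayes
#' factor for presence on the `2 ln` scale with its Kass-Raftery label.
#' The node's unconstrained posterior state probabilities are computed from
#' a standard MCMC run alongside.
#'
#' @inheritParams mcmc_multistate
#' @param taxa taxon set defining the node.
#' @param n_repeats marginal-likelihood replicates (different seeds); if
#'   greater than 1 and the spread exceeds 0.5 log units the result is
#'   flagged unstable.
#' @return list of class `bayes_asr`: `taxa`, `p_present`, `p_absent`,
#'   `logML_present`, `logML_absent`, `bayes_factor`, `label`, `unstable`,
#'   `acceptance`, `config`, `seed`.
#' @export
fossil_test <- function(sample, states, taxa, prior = NULL,
                        config = bayes_control(), seed = NULL,
                        root_prior = "equal", n_repeats = 1) {
  validate_tree_sample(sample)
  if (!is.null(seed)) set.seed(seed)
  prior <- prior %||% empirical_rate_prior(sample, states, config$prior_mult)
  chain <- mcmc_multistate(sample, states, prior, config,
                           seed = sample.int(2^30, 1), root_prior = root_prior)
  post <- mrca_state_posterior(chain, sample, states, taxa, root_prior)
  run_ml <- function(fix_state, sd) {
    if (config$ml_method == "harmonic") {
      cache <- bayes_cache(sample, states, taxa)
      burnin <- floor(config$iters * config$burnin_frac)
      res <- run_chain(cache, prior, config$iters, config$thin, burnin,
                       config$tree_move_prob, root_prior, fix_state = fix_state)
      harmonic_logml(res$draws)
    } else {
      stepping_stone(sample, states, prior, config, fix_taxa = taxa,
                     fix_state = fix_state, root_prior = root_prior,
                     seed = sd)$logML
    }
  }
  seeds <- sample.int(2^30, n_repeats)
  ml1 <- vapply(seeds, function(sd) run_ml(1L, sd), numeric(1))
  ml0 <- vapply(seeds, function(sd) run_ml(0L, sd), numeric(1))
  unstable <- n_repeats > 1 && (sd(ml1) > 0.5 || sd(ml0) > 0.5)
  bf <- 2 * (mean(ml1) - mean(ml0))
  structure(list(taxa = taxa, p_present = unname(post["p_present"]),
                 p_absent = unname(post["p_absent"]),
                 logML_present = mean(ml1), logML_absent = mean(ml0),
                 bayes_factor = bf, label = bayes_factor_label(bf),
                 unstable = unstable, acceptance = chain$acceptance,
                 prior = prior, config = config, seed = seed),
            class = "bayes_asr")
}

#' @export
print.bayes_asr <- function(x, ...) {
  cat(sprintf("Fossil test at MRCA of {%s}:\n", paste(x$taxa, collapse = ", ")))
  cat(sprintf("  p(present) = %.3f, p(absent) = %.3f\n", x$p_present, x$p_absent))
  cat(sprintf("  2 ln BF (presence) = %.3f ('%s')%s\n", x$bayes_factor, x$label,
              if (x$unstable) " [UNSTABLE]" else ""))
  invisible(x)
}
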