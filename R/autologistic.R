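#' Autologistic model parameters
#'
#' The dual-graph autologistic model gives each society a conditional
#' log-odds of carrying the trait,
#' `beta + lambda * (phylogenetic-neighbour term) + theta * (spatial-neighbour term)`,
#' where `beta` controls overall frequency of occurrence, `lambda` the
#' influence of linguistic relatives and `theta` the influence of spatial
#' neighbours. Neighbour terms are sums of neighbour states, either raw
#' (`weights = "sum"`, the default) or divided by the graph's mean degree
#' (`weights = "scaled"`, which keeps a given `lambda` comparable across
#' graph densities and avoids degenerate all-present fields on dense
#' graphs).
#'
#' @param beta,lambda,theta finite reals.
#' @return named numeric vector of class `autologistic_params`.
#' @export
autologistic_params <- function(beta = 0, lambda = 0, theta = 0) {
  p <- c(beta = unname(beta), lambda = unname(lambda), theta = unname(theta))
  if (!all(is.finite(p))) stop("parameters must be finite")
  structure(p, class = "autologistic_params")
}

graph_weight <- function(g, weights) {
  switch(weights, sum = 1, scaled = {
    d <- mean_degree(g)
    if (d == 0) 1 else 1 / d
  }, stop("unknown weights option: ", weights))
}

#' Conditional presence probability at one node
#'
#' `P(x_i = 1 | rest) = logistic(beta + lambda * n_phylo_i + theta * n_spatial_i)`
#' where `n_*_i` are the (possibly scaled) counts of present neighbours of
#' `i` in each graph.
#'
#' @param x binary state vector named by society (node `i` may be `NA`).
#' @param i society label.
#' @param params an [autologistic_params()] vector.
#' @param g_phylo,g_spatial `neighbor_graph`s sharing the node set.
#' @param weights `"sum"` or `"scaled"` neighbour terms.
#' @return a probability.
#' @export
autologistic_conditional <- function(x, i, params, g_phylo, g_spatial,
                                     weights = "sum") {
  if (!i %in% g_phylo$nodes || !i %in% g_spatial$nodes)
    stop("node '", i, "' not in graphs")
  nb <- function(g) {
    e <- g$edges
    others <- c(e[e[, 1] == i, 2], e[e[, 2] == i, 1])
    sum(x[others], na.rm = FALSE) * graph_weight(g, weights)
  }
  plogis(params[["beta"]] + params[["lambda"]] * nb(g_phylo) +
           params[["theta"]] * nb(g_spatial))
}

#' Gibbs sampler for autologistic trait fields
#'
#' Single-site full-conditional updates in fixed ascending label order;
#' after `burnin` sweeps, every `thin`-th sweep is recorded. With the
#' sampling scheme of 51000 sweeps, 1000 burn-in and interval 2 this
#' yields 25000 realizations.
#'
#' @param g_phylo,g_spatial `neighbor_graph`s on the same societies.
#' @param params an [autologistic_params()] vector.
#' @param sweeps total Gibbs sweeps (> `burnin`).
#' @param thin recording interval in sweeps (>= 1).
#' @param burnin sweeps discarded before recording.
#' @param seed optional integer seed.
#' @param init optional initial 0/1 vector named by society; default random.
#' @param weights `"sum"` or `"scaled"` neighbour terms.
#' @return integer matrix, `(sweeps - burnin) / thin` rows, one column per
#'   society (ascending label order).
#' @export
gibbs_field <- function(g_phylo, g_spatial, params, sweeps, thin = 1,
                        burnin = 0, seed = NULL, init = NULL, weights = "sum") {
  if (!setequal(g_phylo$nodes, g_spatial$nodes))
    stop("graphs have different node sets")
  if (thin < 1) stop("thin must be >= 1")
  if (sweeps <= burnin) stop("sweeps must exceed burnin")
  nodes <- sort(g_phylo$nodes)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- rbinom(length(nodes), 1, 0.5)
  else init <- as.integer(init[nodes])
  out <- .gibbs_field_cpp(adjacency_lists(g_phylo, nodes),
                          adjacency_lists(g_spatial, nodes),
                          params[["beta"]], params[["lambda"]], params[["theta"]],
                          graph_weight(g_phylo, weights),
                          graph_weight(g_spatial, weights),
                          as.integer(sweeps), as.integer(thin),
                          as.integer(burnin), init)
  colnames(out) <- nodes
  out
}

#' Census of Gibbs sweeps over all configurations
#'
#' For small graphs (<= 25 societies): runs the sampler and tabulates every
#' post-burn-in sweep as a count per configuration, for comparison against
#' the exact Boltzmann distribution.
#'
#' @inheritParams gibbs_field
#' @return numeric vector of length `2^n`; entry `k + 1` counts the
#'   configuration whose bits (society `j` present = bit `j - 1`, ascending
#'   label order) encode `k`.
#' @export
gibbs_state_census <- function(g_phylo, g_spatial, params, sweeps,
                               burnin = 0, seed = NULL, weights = "sum") {
  nodes <- sort(g_phylo$nodes)
  if (!is.null(seed)) set.seed(seed)
  init <- rbinom(length(nodes), 1, 0.5)
  .gibbs_census_cpp(adjacency_lists(g_phylo, nodes),
                    adjacency_lists(g_spatial, nodes),
                    params[["beta"]], params[["lambda"]], params[["theta"]],
                    graph_weight(g_phylo, weights),
                    graph_weight(g_spatial, weights),
                    as.integer(sweeps), as.integer(burnin), init)
}

# sufficient statistics (sum x, w_p * sum_{E_p} x_i x_j, w_s * sum_{E_s} x_i x_j)
# X: matrix of fields (rows = samples, cols = nodes in ascending order)
suff_stats <- function(X, g_phylo, g_spatial, weights = "sum") {
  nodes <- colnames(X)
  edge_term <- function(g) {
    if (!nrow(g$edges)) return(numeric(nrow(X)))
    i <- match(g$edges[, 1], nodes); j <- match(g$edges[, 2], nodes)
    rowSums(X[, i, drop = FALSE] * X[, j, drop = FALSE]) * graph_weight(g, weights)
  }
  cbind(level = rowSums(X), phylo = edge_term(g_phylo), spatial = edge_term(g_spatial))
}

# per-node present-neighbour counts for each graph (weighted)
neighbour_counts <- function(x, g, weights = "sum") {
  nodes <- names(x)
  cnt <- setNames(numeric(length(x)), nodes)
  if (nrow(g$edges)) {
    i <- match(g$edges[, 1], nodes); j <- match(g$edges[, 2], nodes)
    for (k in seq_along(i)) {
      cnt[i[k]] <- cnt[i[k]] + x[j[k]]
      cnt[j[k]] <- cnt[j[k]] + x[i[k]]
    }
  }
  cnt * graph_weight(g, weights)
}

#' Control settings for the autologistic fit
#'
#' @param n_samples Gibbs fields per Monte Carlo likelihood iteration.
#' @param thin sweeps between recorded fields.
#' @param burnin burn-in sweeps per Gibbs run.
#' @param max_iter maximum reference-parameter updates of the Monte Carlo
#'   maximum-likelihood loop.
#' @param tol stop when the largest parameter step falls below this.
#' @param level confidence level for the intervals behind the +/-/0 call.
#' @param weights `"sum"` or `"scaled"` neighbour terms.
#' @return a list of class `autologistic_control`.
#' @export
autologistic_control <- function(n_samples = 2000, thin = 10, burnin = 2000,
                                 max_iter = 4, tol = 0.01, level = 0.95,
                                 weights = "sum") {
  structure(list(n_samples = n_samples, thin = thin, burnin = burnin,
                 max_iter = max_iter, tol = tol, level = level,
                 weights = weights), class = "autologistic_control")
}

pseudo_fit <- function(x, g_phylo, g_spatial, weights, level) {
  np <- neighbour_counts(x, g_phylo, weights)
  ns <- neighbour_counts(x, g_spatial, weights)
  fit <- suppressWarnings(stats::glm(x ~ np + ns, family = stats::binomial()))
  est <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  est[!is.finite(est)] <- 0
  se[!is.finite(se)] <- Inf
  z <- qnorm(1 - (1 - level) / 2)
  list(est = setNames(as.numeric(est), c("beta", "lambda", "theta")),
       se = setNames(as.numeric(se), c("beta", "lambda", "theta")),
       lower = est - z * se, upper = est + z * se,
       converged = fit$converged)
}

log_mean_exp <- function(v) {
  mx <- max(v)
  mx + log(mean(exp(v - mx)))
}

#' Fit the autologistic model to one trait
#'
#' Default method is Monte Carlo maximum likelihood: the joint model is the
#' exponential family `P(x) ~ exp(beta*S1 + lambda*S2 + theta*S3)` with
#' sufficient statistics (number of presences, co-present phylogenetic
#' pairs, co-present spatial pairs). The intractable normaliser ratio is
#' approximated by importance weights over Gibbs-sampled fields generated
#' at a reference parameter, which is iterated to the current optimum until
#' it stabilises. Uncertainty comes from the estimated Fisher information
#' (the covariance of the sufficient statistics under the fitted model);
#' each parameter is classified `+` if its central interval lies above 0,
#' `-` if below, else `0`. Maximum pseudolikelihood (a logistic regression
#' of each society's state on its neighbour counts) is available as a fast
#' cross-check and supplies the starting value.
#'
#' @param x binary trait vector named by society, defined on all graph
#'   nodes and non-constant.
#' @param g_phylo,g_spatial `neighbor_graph`s on the same societies.
#' @param method `"mcmle"` or `"pseudolikelihood"`.
#' @param control an [autologistic_control()] list.
#' @param seed optional integer seed.
#' @param trait optional trait id carried into the result.
#' @return object of class `autologistic_fit`: estimates, standard errors,
#'   intervals, sign classification, method, convergence flag, seed.
#' @export
fit_autologistic <- function(x, g_phylo, g_spatial,
                             method = c("mcmle", "pseudolikelihood"),
                             control = autologistic_control(), seed = NULL,
                             trait = NA_character_) {
  method <- match.arg(method)
  if (!setequal(g_phylo$nodes, g_spatial$nodes))
    stop("graphs have different node sets")
  nodes <- sort(g_phylo$nodes)
  if (is.null(names(x))) stop("trait vector must be named by society")
  missing <- setdiff(nodes, names(x))
  if (length(missing))
    stop("trait undefined for: ", paste(missing, collapse = ", "))
  x <- as.integer(x[nodes]); names(x) <- nodes
  if (anyNA(x)) stop("trait has missing values on graph nodes")
  if (length(unique(x)) < 2L) stop("constant trait: autologistic fit undefined")
  if (!is.null(seed)) set.seed(seed)
  level <- control$level
  pf <- pseudo_fit(x, g_phylo, g_spatial, control$weights, level)
  if (method == "pseudolikelihood") {
    return(new_autologistic_fit(trait, pf$est, pf$se, pf$lower, pf$upper,
                                level, "pseudolikelihood", pf$converged, seed))
  }
  s_obs <- drop(suff_stats(matrix(x, 1, dimnames = list(NULL, nodes)),
                           g_phylo, g_spatial, control$weights))
  psi <- pmin(pmax(pf$est, -5), 5)  # clamp degenerate separation fits
  converged <- FALSE
  step <- Inf
  S <- NULL
  for (it in seq_len(control$max_iter)) {
    X <- gibbs_field(g_phylo, g_spatial,
                     autologistic_params(psi[1], psi[2], psi[3]),
                     sweeps = control$burnin + control$n_samples * control$thin,
                     thin = control$thin, burnin = control$burnin,
                     weights = control$weights)
    S <- suff_stats(X, g_phylo, g_spatial, control$weights)
    negll <- function(th) {
      d <- th - psi
      -(sum(d * s_obs) - log_mean_exp(drop(S %*% d)))
    }
    grad <- function(th) {
      d <- th - psi
      lw <- drop(S %*% d); lw <- lw - max(lw)
      w <- exp(lw) / sum(exp(lw))
      -(s_obs - drop(crossprod(S, w)))
    }
    # trust region: the Monte Carlo likelihood ratio is only reliable near
    # the reference parameter (and is unbounded when the observed statistic
    # lies on the sampled hull boundary), so steps are box-limited
    opt <- optim(psi, negll, grad, method = "L-BFGS-B",
                 lower = psi - 2, upper = psi + 2,
                 control = list(maxit = 200))
    step <- max(abs(opt$par - psi))
    psi <- opt$par
    if (step < control$tol) { converged <- TRUE; break }
  }
  # Monte Carlo jitter keeps successive estimates from coinciding exactly;
  # genuine divergence shows up as the optimiser railing the trust region
  # on its final pass
  if (!converged) converged <- step < 2 - 1e-8
  # information = Var of sufficient statistics under the fitted model;
  # redraw at the optimum for a clean variance estimate
  X <- gibbs_field(g_phylo, g_spatial,
                   autologistic_params(psi[1], psi[2], psi[3]),
                   sweeps = control$burnin + control$n_samples * control$thin,
                   thin = control$thin, burnin = control$burnin,
                   weights = control$weights)
  S <- suff_stats(X, g_phylo, g_spatial, control$weights)
  info <- cov(S)
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(Inf, 3))
  z <- qnorm(1 - (1 - level) / 2)
  est <- setNames(psi, c("beta", "lambda", "theta"))
  se <- setNames(se, c("beta", "lambda", "theta"))
  new_autologistic_fit(trait, est, se, est - z * se, est + z * se,
                       level, "mcmle", converged, seed)
}

new_autologistic_fit <- function(trait, est, se, lower, upper, level,
                                 method, converged, seed) {
  sign <- ifelse(lower > 0, "+", ifelse(upper < 0, "-", "0"))
  structure(list(trait = trait, estimate = est, se = se,
                 lower = setNames(as.numeric(lower), names(est)),
                 upper = setNames(as.numeric(upper), names(est)),
                 sign = setNames(sign, names(est)), level = level,
                 method = method, converged = converged, seed = seed),
            class = "autologistic_fit")
}

#' @export
print.autologistic_fit <- function(x, ...) {
  cat("Autologistic fit (", x$method, ")",
      if (!is.na(x$trait)) paste0(" for ", x$trait), ":\n", sep = "")
  tab <- data.frame(estimate = x$estimate, se = x$se, lower = x$lower,
                    upper = x$upper, sign = x$sign)
  print(round(tab[, 1:4], 3))
  cat("signs:", paste(names(x$sign), x$sign, collapse = ", "),
      if (!x$converged) "(NOT converged)", "\n")
  invisible(x)
}

#' Fit the autologistic model to every trait of a matrix
#'
#' @param m a `trait_matrix` whose rows cover the graph nodes.
#' @param g_phylo,g_spatial `neighbor_graph`s.
#' @param traits trait ids to fit (default all columns).
#' @inheritParams fit_autologistic
#' @return data frame, one row per trait: estimates, interval bounds and
#'   sign classification for beta/lambda/theta, method, converged, error.
#' @export
fit_autologistic_all <- function(m, g_phylo, g_spatial, traits = colnames(m),
                                 method = "mcmle",
                                 control = autologistic_control(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trait_seeds <- setNames(sample.int(.Machine$integer.max, length(traits)), traits)
  rows <- lapply(traits, function(tr) {
    x <- setNames(unclass(m)[, tr], rownames(m))
    x <- x[names(x) %in% g_phylo$nodes]
    fit <- tryCatch(
      fit_autologistic(x, g_phylo, g_spatial, method = method,
                       control = control, seed = trait_seeds[[tr]], trait = tr),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(trait = tr, beta = NA_real_, lambda = NA_real_,
                        theta = NA_real_, beta_lo = NA_real_, beta_hi = NA_real_,
                        lambda_lo = NA_real_, lambda_hi = NA_real_,
                        theta_lo = NA_real_, theta_hi = NA_real_,
                        beta_sign = NA_character_, lambda_sign = NA_character_,
                        theta_sign = NA_character_, converged = NA,
                        error = conditionMessage(fit), stringsAsFactors = FALSE))
    }
    data.frame(trait = tr, beta = fit$estimate[["beta"]],
               lambda = fit$estimate[["lambda"]], theta = fit$estimate[["theta"]],
               beta_lo = fit$lower[["beta"]], beta_hi = fit$upper[["beta"]],
               lambda_lo = fit$lower[["lambda"]], lambda_hi = fit$upper[["lambda"]],
               theta_lo = fit$lower[["theta"]], theta_hi = fit$upper[["theta"]],
               beta_sign = fit$sign[["beta"]], lambda_sign = fit$sign[["lambda"]],
               theta_sign = fit$sign[["theta"]], converged = fit$converged,
               error = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Contingency of phylogenetic vs spatial sign calls
#'
#' Cross-tabulates the +/-/0 classification of the phylogenetic (`lambda`)
#' and spatial (`theta`) parameters over fitted traits.
#'
#' @param fits the data frame from [fit_autologistic_all()].
#' @return a 3x3 table (rows `lambda` sign, columns `theta` sign).
#' @export
sign_contingency <- function(fits) {
  lv <- c("+", "-", "0")
  table(phylo = factor(fits$lambda_sign, lv),
        spatial = factor(fits$theta_sign, lv))
}
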