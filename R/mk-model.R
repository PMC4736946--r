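#' Two-state Mk model of trait evolution
#'
#' A continuous-time Markov model for a binary trait with gain rate `q01`
#' (absent to present) and loss rate `q10`, in events per unit branch
#' length. `Mk1` constrains the two rates to be equal; `Mk2` estimates them
#' separately.
#'
#' @param q01,q10 non-negative rates; `Mk1` requires `q01 == q10`.
#' @param kind `"Mk1"` or `"Mk2"` (inferred from the rates if omitted).
#' @param log_likelihood optional log-likelihood attached by the fitters.
#' @return list of class `mk_model`.
#' @export
mk_model <- function(q01, q10 = q01, kind = NULL, log_likelihood = NA_real_) {
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0")
  if (is.null(kind)) kind <- if (isTRUE(all.equal(q01, q10))) "Mk1" else "Mk2"
  if (kind == "Mk1" && !isTRUE(all.equal(q01, q10)))
    stop("Mk1 requires q01 == q10")
  structure(list(kind = kind, q01 = q01, q10 = q10,
                 log_likelihood = log_likelihood), class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat(sprintf("%s model: q01 (gain) = %.5g, q10 (loss) = %.5g, logL = %.4f\n",
              x$kind, x$q01, x$q10, x$log_likelihood))
  invisible(x)
}

#' Transition probabilities over a branch
#'
#' Closed form for the 2-state chain: with `r = q01 + q10` and stationary
#' frequency `pi1 = q01 / r`,
#' `P(0 -> 1) = pi1 (1 - exp(-r t))` and `P(1 -> 1) = pi1 + (1 - pi1) exp(-r t)`.
#'
#' @param model an `mk_model` (or list with `q01`, `q10`).
#' @param t branch length `>= 0`.
#' @return 2x2 matrix, rows = ancestral state (0, 1), rows sum to 1.
#' @export
mk_transition_matrix <- function(model, t) {
  if (t < 0) stop("branch length must be >= 0")
  r <- model$q01 + model$q10
  if (r == 0)
    return(matrix(c(1, 0, 0, 1), 2, 2,
                  dimnames = list(c("0", "1"), c("0", "1"))))
  pi1 <- model$q01 / r
  e <- exp(-r * t)
  matrix(c(1 - pi1 * (1 - e), (1 - pi1) * (1 - e),
           pi1 * (1 - e), pi1 + (1 - pi1) * e),
         2, 2, dimnames = list(c("0", "1"), c("0", "1")))
}

mk_root_prior <- function(model, root_prior) {
  switch(root_prior,
         equal = c(0.5, 0.5),
         stationary = {
           r <- model$q01 + model$q10
           if (r == 0) c(0.5, 0.5) else c(model$q10, model$q01) / r
         },
         stop("unknown root prior: ", root_prior))
}

# tip partial-likelihood rows: NA -> (1,1)
tip_partials <- function(states) {
  L <- cbind(as.numeric(is.na(states) | states == 0),
             as.numeric(is.na(states) | states == 1))
  L
}

# Felsenstein pruning pass. Returns per-node normalised partials and the
# per-node log scaling factors; info from postorder_info().
prune_pass <- function(info, tipL, q01, q10, fix_node = NULL, fix_state = NULL) {
  L <- matrix(1, info$n_node, 2)
  L[seq_len(info$n_tip), ] <- tipL
  logscale <- numeric(info$n_node)
  r <- q01 + q10
  pi1 <- if (r == 0) 0.5 else q01 / r
  el <- info$edge_len
  e <- exp(-r * el)
  # transition rows as functions of child partials:
  # m[anc] = sum_child P[anc, child] * L[child]
  for (v in info$post_nodes) {
    prod0 <- 1; prod1 <- 1; ls <- 0
    for (ch in info$children[[v]]) {
      ech <- if (is.na(e[ch])) 1 else e[ch]
      p01 <- pi1 * (1 - ech); p00 <- 1 - p01
      p11 <- pi1 + (1 - pi1) * ech; p10 <- 1 - p11
      m0 <- p00 * L[ch, 1] + p01 * L[ch, 2]
      m1 <- p10 * L[ch, 1] + p11 * L[ch, 2]
      prod0 <- prod0 * m0; prod1 <- prod1 * m1
      ls <- ls + logscale[ch]
    }
    if (!is.null(fix_node) && v == fix_node) {
      if (fix_state == 0) prod1 <- 0 else prod0 <- 0
    }
    s <- prod0 + prod1
    if (s <= 0) { logscale[v] <- -Inf; L[v, ] <- c(0.5, 0.5) }
    else { L[v, ] <- c(prod0, prod1) / s; logscale[v] <- ls + log(s) }
  }
  list(L = L, logscale = logscale)
}

#' Log-likelihood of a binary trait on a tree
#'
#' Felsenstein pruning under the 2-state Mk model; tips with a missing
#' state contribute a flat partial likelihood `(1, 1)`. The root partials
#' are combined with an equal or stationary prior. Optionally the state at
#' an internal node can be fixed (`fossilised`), which zeroes the partial
#' likelihood of the other state at that node.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param states binary/missing tip states named by tip label.
#' @param model an `mk_model`.
#' @param root_prior `"equal"` (default) or `"stationary"`.
#' @param fix optional list `list(node = <internal node index>, state = 0 or 1)`.
#' @return the log-likelihood.
#' @export
tree_loglik <- function(tree, states, model, root_prior = c("equal", "stationary"),
                        fix = NULL) {
  root_prior <- match.arg(root_prior)
  s <- match_tip_states(tree, states, allow_missing = TRUE)
  if (all(is.na(s))) stop("all tip states missing")
  info <- postorder_info(tree)
  pp <- prune_pass(info, tip_partials(s), model$q01, model$q10,
                   fix_node = fix$node, fix_state = fix$state)
  prior <- mk_root_prior(model, root_prior)
  lik <- sum(prior * pp$L[info$root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pp$logscale[info$root]
}

rate_bounds <- c(1e-8, 100)

#' Maximum-likelihood Mk fit
#'
#' Optimises the rate(s) on the log scale within `[1e-8, 100]` changes per
#' unit branch length; the 2-parameter model uses bounded quasi-Newton
#' search from three starting points to avoid local optima.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param states binary/missing tip states named by tip label.
#' @param kind `"Mk1"` (single rate) or `"Mk2"` (separate gain/loss rates).
#' @param root_prior `"equal"` or `"stationary"`.
#' @return a fitted `mk_model` with `log_likelihood` set.
#' @export
fit_mk <- function(tree, states, kind = c("Mk1", "Mk2"),
                   root_prior = "equal") {
  kind <- match.arg(kind)
  s <- match_tip_states(tree, states, allow_missing = TRUE)
  info <- postorder_info(tree)
  tipL <- tip_partials(s)
  lb <- log(rate_bounds[1]); ub <- log(rate_bounds[2])
  ll <- function(q01, q10) {
    pp <- prune_pass(info, tipL, q01, q10)
    prior <- mk_root_prior(list(q01 = q01, q10 = q10), root_prior)
    lik <- sum(prior * pp$L[info$root, ])
    if (lik <= 0) -Inf else log(lik) + pp$logscale[info$root]
  }
  if (kind == "Mk1") {
    opt <- optimize(function(lq) -ll(exp(lq), exp(lq)), c(lb, ub))
    q <- exp(opt$minimum)
    return(mk_model(q, q, "Mk1", -opt$objective))
  }
  starts <- list(log(c(0.001, 0.001)), log(c(0.1, 0.1)), log(c(1, 0.05)))
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      optim(st, function(lq) -ll(exp(lq[1]), exp(lq[2])), method = "L-BFGS-B",
            lower = lb, upper = ub),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {  # grid-refinement fallback
    grid <- expand.grid(lq1 = seq(lb, ub, length.out = 25),
                        lq2 = seq(lb, ub, length.out = 25))
    vals <- mapply(function(a, b) -ll(exp(a), exp(b)), grid$lq1, grid$lq2)
    k <- which.min(vals)
    best <- list(par = c(grid$lq1[k], grid$lq2[k]), value = vals[k])
  }
  mk_model(exp(best$par[1]), exp(best$par[2]), "Mk2", -best$value)
}

#' Fit Mk1 and Mk2 and select by likelihood-ratio test
#'
#' The asymmetric-rates model is retained only when the likelihood-ratio
#' statistic `2 (lnL_Mk2 - lnL_Mk1)` exceeds the chi-square(1) critical
#' value at `alpha`; otherwise the symmetric single-rate model is kept.
#'
#' @inheritParams fit_mk
#' @param alpha test size for preferring Mk2.
#' @return the selected `mk_model`, with attributes `lrt` (statistic),
#'   `p_value` and `alternative` (the unselected fit).
#' @export
fit_and_select <- function(tree, states, alpha = 0.05, root_prior = "equal") {
  m1 <- fit_mk(tree, states, "Mk1", root_prior)
  m2 <- fit_mk(tree, states, "Mk2", root_prior)
  lrt <- max(0, 2 * (m2$log_likelihood - m1$log_likelihood))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  chosen <- if (lrt > qchisq(1 - alpha, 1)) m2 else m1
  attr(chosen, "lrt") <- lrt
  attr(chosen, "p_value") <- p
  attr(chosen, "alternative") <- if (chosen$kind == "Mk1") m2 else m1
  chosen
}

#' Marginal ancestral-state probabilities
#'
#' Posterior probability of the trait being present at every internal
#' node, integrating over all other nodes' states, via the standard
#' up-down (re-rooting) algorithm: a pruning pass computes each node's
#' below-partials, a preorder pass propagates the above-partials, and the
#' marginal at a node is the normalised product combined with the root
#' prior.
#'
#' @inheritParams tree_loglik
#' @return named numeric vector of `P(present)` for internal nodes
#'   (ape node indices `Ntip+1 ... Ntip+Nnode`).
#' @export
marginal_node_probs <- function(tree, states, model,
                                root_prior = c("equal", "stationary"),
                                fix = NULL) {
  root_prior <- match.arg(root_prior)
  s <- match_tip_states(tree, states, allow_missing = TRUE)
  info <- postorder_info(tree)
  pp <- prune_pass(info, tip_partials(s), model$q01, model$q10,
                   fix_node = fix$node, fix_state = fix$state)
  prior <- mk_root_prior(model, root_prior)
  r <- model$q01 + model$q10
  pi1 <- if (r == 0) 0.5 else model$q01 / r
  e <- exp(-r * info$edge_len)
  U <- matrix(NA_real_, info$n_node, 2)
  U[info$root, ] <- prior
  # preorder: parents before children
  for (v in rev(info$post_nodes)) {
    kids <- info$children[[v]]
    # messages m_b[anc state] for each child b
    msg <- lapply(kids, function(ch) {
      ech <- if (is.na(e[ch])) 1 else e[ch]
      p01 <- pi1 * (1 - ech); p11 <- pi1 + (1 - pi1) * ech
      c((1 - p01) * pp$L[ch, 1] + p01 * pp$L[ch, 2],
        (1 - p11) * pp$L[ch, 1] + p11 * pp$L[ch, 2])
    })
    for (j in seq_along(kids)) {
      ch <- kids[j]
      if (ch <= info$n_tip) next
      G <- U[v, ]
      for (k in seq_along(kids)) if (k != j) G <- G * msg[[k]]
      if (!is.null(fix) && v == fix$node)
        G[if (fix$state == 0) 2 else 1] <- 0
      ech <- if (is.na(e[ch])) 1 else e[ch]
      p01 <- pi1 * (1 - ech); p11 <- pi1 + (1 - pi1) * ech
      u <- c(G[1] * (1 - p01) + G[2] * (1 - p11),
             G[1] * p01 + G[2] * p11)
      if (sum(u) > 0) u <- u / sum(u)
      U[ch, ] <- u
    }
  }
  internal <- seq.int(info$n_tip + 1L, info$n_node)
  post <- U[internal, , drop = FALSE] * pp$L[internal, , drop = FALSE]
  out <- post[, 2] / rowSums(post)
  names(out) <- as.character(internal)
  out
}
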