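test_that("conditional probability matches the logistic form", {
  g <- toy_dual_graphs(6)
  nodes <- sort(g$phylo$nodes)
  x <- setNames(c(1L, 0L, 0L, 0L, 0L, 0L), nodes)
  p0 <- autologistic_params(0, 0, 0)
  expect_equal(autologistic_conditional(x, nodes[3], p0, g$phylo, g$spatial), 0.5)
  # node 2 has phylo neighbours 1 and 3 (ring); only node 1 present
  p1 <- autologistic_params(0, 1, 0)
  x_sp0 <- x
  x_sp0[c(4, 5)] <- 0L  # spatial neighbours of node 2 absent anyway
  expect_equal(autologistic_conditional(x_sp0, nodes[2], p1, g$phylo, g$spatial),
               plogis(1))
  pneg <- autologistic_params(-30, 0, 0)
  expect_lt(autologistic_conditional(x, nodes[3], pneg, g$phylo, g$spatial), 1e-12)
  expect_error(autologistic_conditional(x, "zzz", p0, g$phylo, g$spatial),
               "not in graphs")
})

test_that("gibbs sampler reduces to independent coin flips when couplings vanish", {
  g <- toy_dual_graphs(10)
  beta <- 0.7
  X <- gibbs_field(g$phylo, g$spatial, autologistic_params(beta, 0, 0),
                   sweeps = 6000, thin = 1, burnin = 500, seed = 2)
  p <- plogis(beta)
  n_draws <- nrow(X) * ncol(X)
  expect_equal(mean(X), p, tolerance = 3 * sqrt(p * (1 - p) / n_draws) / p + 0.01)
  # per-sweep totals follow Binomial(10, p): chi-square goodness of fit
  tot <- table(factor(rowSums(X), levels = 0:10))
  expected <- dbinom(0:10, 10, p) * nrow(X)
  keep <- expected > 5
  chi <- sum((tot[keep] - expected[keep])^2 / expected[keep])
  expect_lt(chi, qchisq(0.999, sum(keep) - 1))
  # determinism under seed
  X2 <- gibbs_field(g$phylo, g$spatial, autologistic_params(beta, 0, 0),
                    sweeps = 6000, thin = 1, burnin = 500, seed = 2)
  expect_identical(X, X2)
})

test_that("the sampling schedule yields the expected number of realizations", {
  g <- toy_dual_graphs(5)
  X <- gibbs_field(g$phylo, g$spatial, autologistic_params(0, 0.1, 0.1),
                   sweeps = 51000, thin = 2, burnin = 1000, seed = 1)
  expect_equal(nrow(X), 25000)
  expect_error(gibbs_field(g$phylo, g$spatial, autologistic_params(0, 0, 0),
                           sweeps = 100, thin = 1, burnin = 100), "exceed")
  expect_error(gibbs_field(g$phylo, g$spatial, autologistic_params(0, 0, 0),
                           sweeps = 100, thin = 0, burnin = 10), "thin")
})

test_that("gibbs stationary law matches exact Boltzmann enumeration", {
  g <- toy_dual_graphs(8)
  cen <- gibbs_state_census(g$phylo, g$spatial,
                            autologistic_params(-0.3, 0.5, 0.3),
                            sweeps = 2e5, burnin = 1000, seed = 11)
  ex <- oracle_autologistic_dist(g$phylo, g$spatial, -0.3, 0.5, 0.3)
  tv <- 0.5 * sum(abs(cen / sum(cen) - ex))
  expect_lt(tv, 0.03)
})

test_that("Monte Carlo MLE agrees with the exact-normaliser MLE on 8 nodes", {
  g <- toy_dual_graphs(8)
  nodes <- sort(g$phylo$nodes)
  # configurations whose observed sufficient statistics admit an interior MLE
  for (code in c(11L, 27L)) {
    x <- setNames(as.integer(intToBits(code))[1:8], nodes)
    exact <- oracle_autologistic_mle(x, g$phylo, g$spatial)
    fit <- fit_autologistic(x, g$phylo, g$spatial,
                            control = autologistic_control(n_samples = 4000,
                                                           thin = 10,
                                                           burnin = 2000),
                            seed = 100 + code)
    expect_lt(max(abs(fit$estimate - exact)), 0.15)
    # intervals contain the point estimates; signs follow the interval rule
    expect_true(all(fit$lower <= fit$estimate & fit$estimate <= fit$upper))
    expect_identical(unname(fit$sign),
                     unname(ifelse(fit$lower > 0, "+",
                                   ifelse(fit$upper < 0, "-", "0"))))
  }
})

test_that("independent coin-flip traits are classified neutral for both graphs", {
  meta <- sim_metadata(n = 30, n_subfamilies = 6, seed = 5)
  gs <- build_spatial_graph(meta, 1200)
  gp <- build_phylo_graph(meta)
  ctrl <- autologistic_control(n_samples = 1000, thin = 5, burnin = 1000,
                               weights = "scaled")
  set.seed(99)
  signs <- t(vapply(1:10, function(r) {
    x <- setNames(rbinom(30, 1, 0.5), meta$society)
    if (length(unique(x)) < 2) x[1] <- 1L - x[1]
    f <- fit_autologistic(x, gp, gs, control = ctrl, seed = 300 + r)
    c(f$sign[["lambda"]], f$sign[["theta"]])
  }, character(2)))
  expect_gte(mean(signs[, 1] == "0"), 0.8)
  expect_gte(mean(signs[, 2] == "0"), 0.8)
})

test_that("pseudolikelihood fit maximises the product of conditionals", {
  meta <- sim_metadata(n = 40, n_subfamilies = 6, seed = 8)
  gs <- build_spatial_graph(meta, 1200)
  gp <- build_phylo_graph(meta)
  m <- sim_autologistic_traits(gp, gs, -0.3, 0.4, 0.2, n_traits = 1, seed = 10,
                               weights = "scaled")
  x <- setNames(drop(unclass(m)), rownames(m))
  ctrl <- autologistic_control(weights = "scaled")
  f <- fit_autologistic(x, gp, gs, method = "pseudolikelihood", control = ctrl)
  # oracle: optimise the log pseudolikelihood written out longhand
  nodes <- sort(gp$nodes)
  neigh <- function(g) {
    cnt <- setNames(numeric(length(nodes)), nodes)
    for (k in seq_len(nrow(g$edges))) {
      a <- g$edges[k, 1]; b <- g$edges[k, 2]
      cnt[a] <- cnt[a] + x[b]; cnt[b] <- cnt[b] + x[a]
    }
    cnt / mean_degree(g)
  }
  np <- neigh(gp); ns <- neigh(gs); xv <- x[nodes]
  npl <- function(th) {
    eta <- th[1] + th[2] * np + th[3] * ns
    -sum(xv * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0, 0), npl, method = "BFGS")
  expect_lt(max(abs(f$estimate - opt$par)), 0.02)
  expect_error(fit_autologistic(setNames(rep(1L, 40), meta$society), gp, gs),
               "constant")
})
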