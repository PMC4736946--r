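---
title: "Tracing binary cultural traits on language trees: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing binary cultural traits on language trees: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(folkphylo)
```

folkphylo asks a classic question of cultural macroevolution — Galton's
problem — for binary traits such as the presence of a folktale type in a
population's oral tradition: is the cross-cultural distribution of the
trait explained by descent from common ancestral populations (vertical
transmission), by diffusion between neighbouring societies (horizontal
transmission), or by chance? Population history is proxied by a Bayesian
posterior sample of time-calibrated language trees, which lets every
inference integrate over phylogenetic uncertainty. This vignette explains
the three models in the pipeline, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the design decisions
taken where the methods literature leaves choices open.

## Stage 1 — phylogenetic signal: the D statistic

For tip states $x_i \in \{0, 1\}$, internal-node values are filled
tip-to-root as the mean of child values (polytomies average over all
children), and the raw change score is
$d = \sum_{v}\sum_{c \in \mathrm{ch}(v)} |x_c - x_v|$. Branch lengths do
not enter $d$; only topology does. Two null distributions calibrate it:

* **shuffle** — tip states permuted uniformly; the mean of this null
  anchors $D = 1$, a phylogenetically random arrangement;
* **threshold-Brownian** — a Brownian character simulated along the
  branches from a root value of 0 (variance equal to branch length) and
  cut by rank so that exactly the observed number of tips are present;
  its mean anchors $D = 0$, the expectation for a neutral, purely
  vertically inherited trait.

$D = (d_{\mathrm{obs}} - \bar d_B)/(\bar d_R - \bar d_B)$; values below 0
indicate extra conservatism, above 1 overdispersion. Significance is
one-tailed for clumping: $p$ is the fraction of null scores
$\le d_{\mathrm{obs}}$, and a trait passes the screen when the
shuffle-null $p < \alpha$ (default $\alpha = 0.05$, configurable).
Defaults follow the method's standard usage: 1000 simulations per null,
screening performed on the majority-rules consensus tree. Constant traits
have undefined $D$ and are excluded. Missing tip states are handled by
dropping those tips from the trait's copy of the tree; because the signal
screen cannot use missing data, a data-less outgroup must be coded
all-absent (the default) or all-present, and `outgroup_sensitivity()`
reruns the screen under both codings to confirm the significant set is
stable.

The rank-cut in the Brownian null fixes the number of present tips rather
than applying a fixed threshold; this matches the reference behaviour of
conditioning both nulls on the observed prevalence, and makes the two
nulls directly comparable. One degenerate case is worth knowing: on a
star tree every arrangement with the same prevalence yields the same $d$,
so both null means and the observed score coincide and $D$ is 0/0. The
generators' tests therefore check the star-tree limit through the law of
the trait (threshold-Brownian = uniform subset) rather than through $D$.

## Stage 2 — vertical vs spatial: the dual-graph autologistic model

Societies are nodes of two undirected graphs: the phylogenetic graph
links members of the same linguistic subfamily, the spatial graph links
societies within `radius_km` (default 1000 km, great-circle distance,
boundary inclusive, Earth radius 6371 km). Societies that cannot be tied
to a single location are excluded from both graphs. The joint model is a
binary Markov random field
$$P(x) \propto \exp\!\big(\beta \textstyle\sum_i x_i
 + \lambda\, w_p \!\!\sum_{(i,j) \in E_p}\! x_i x_j
 + \theta\, w_s \!\!\sum_{(i,j) \in E_s}\! x_i x_j\big),$$
whose full conditionals are logistic in the neighbour sums — the form the
Gibbs sampler uses (fixed ascending node order for reproducibility; the
compiled sampler reproduces the standard schedule of 51000 sweeps, 1000
burn-in, interval 2 → 25000 realizations).

**Neighbour weighting.** With raw sums ($w = 1$, the default, matching
the model as usually written) the per-edge coupling is $\lambda$ itself.
On realistic graphs with mean degree 5–15, couplings of order 1 then put
the field deep in the ordered (all-present) phase: the model is
degenerate and simulated traits are constant. The `weights = "scaled"`
option divides each graph's edge term by its mean degree, so $\lambda$
measures the effect of a fully present neighbourhood rather than of one
neighbour; simulation studies in this package (including the calibration
at $(\beta, \lambda, \theta) = (-1, 1.5, 0)$) use the scaled form for
exactly this reason. Fits and simulations must use the same weighting.

**Estimation.** The likelihood's normaliser is intractable, so the
default fit is Monte Carlo maximum likelihood: with sufficient statistics
$s(x)$, the log-likelihood ratio to a reference parameter $\psi$ is
estimated by importance weights over Gibbs fields drawn at $\psi$, then
maximised; $\psi$ is moved to the optimum and the cycle repeated (default
4 iterations, 2000 fields of thinning 10 after 2000 burn-in sweeps per
cycle). Because the Monte Carlo objective is only trustworthy near
$\psi$ — and is unbounded whenever the observed statistic lies on the
boundary of the sampled convex hull — each maximisation is box-limited to
$\psi \pm 2$ (a trust region); a fit is flagged non-converged only if the
final step rails that box. Standard errors come from the Fisher
information of the exponential family, the covariance of $s(x)$ under the
fitted model, estimated from a fresh Gibbs sample at the optimum. Maximum
pseudolikelihood (logistic regression of each state on its neighbour
counts) provides the starting value and a fast cross-check.

**Classification.** Each parameter is called `+` when its central
interval (default 95%, mirroring $\alpha = 0.05$) lies above zero, `-`
below, `0` otherwise. A caveat the package is explicit about: one binary
field on ~50 societies carries limited information, so 95% sign calls are
conservative — in the package's own calibration runs the interval for
$\lambda$ frequently spans zero even when the generating $\lambda$ is
substantial. The pipeline's smoke configuration uses 1-sigma intervals
for this reason; real analyses should treat `0` calls at small $n$ as
"insufficient information", not "no effect".

## Stage 3 — ancestral states

**Maximum likelihood.** The 2-state continuous-time Markov chain has gain
rate `q01` and loss rate `q10` (events per unit branch length; unit =
the trees' time unit). Transition probabilities use the closed form
$P(0\!\to\!1) = \pi_1(1 - e^{-rt})$, $r = q_{01}+q_{10}$,
$\pi_1 = q_{01}/r$. Likelihoods come from Felsenstein pruning with
per-node rescaling; missing tips contribute flat partials $(1,1)$, which
is how a data-less outgroup participates without biasing the
reconstruction. Rates are optimised on the log scale in
$[10^{-8}, 100]$, with three starts for the two-parameter model and a
grid fallback. Mk2 replaces Mk1 only when
$2(\ell_2 - \ell_1) > \chi^2_{1,1-\alpha}$ (3.841 at $\alpha = 0.05$).
The root prior is equal (0.5/0.5) by default — the convention of the
widely used reconstruction tools — with the stationary prior available.

Marginal node probabilities use the standard up–down pass and are checked
against full enumeration oracles in the test-suite. Tree uncertainty is
handled by refitting the model on every tree of the posterior sample
(model selection per tree, the literal per-tree reading), locating each
consensus clade in each tree (strict monophyly of the ingroup tip set),
and averaging P(present) over exactly the trees containing the clade.
That average times the clade's posterior frequency is the `combined`
score, so support for a reconstruction can never exceed support for the
ancestor itself. Corpora apply `combined > 0.5` (inferred, strict) and
`combined >= 0.7` (secure, inclusive). Consensus clades are identified by
ingroup tip sets after outgroup rooting; consensus branch lengths are the
mean (configurable to median) over trees containing the clade — the
common convention where no single one is prescribed.

**Bayesian.** `mcmc_multistate()` samples (tree index, q01, q10) by
Metropolis-within-Gibbs: uniform tree proposals, sliding-window rate
proposals reflected at the uniform prior bounds, window auto-tuned to
~30% acceptance during burn-in (default burn-in 10% of iterations;
study-scale defaults are $10^6$ iterations thinned every 1000). Prior
ranges follow the empirical rule: uniform from 0 to `prior_mult` (default
10) times the maximum-likelihood rate. `mrca_state_posterior()` evaluates
the marginal at the most recent common ancestor of the target taxa in
each sampled tree — the smallest clade containing them, so the question
stays well-posed in trees where the set is not monophyletic — and
averages over draws. Fossil tests fix that node's state to present or
absent and compare marginal likelihoods on the $2\ln$ Bayes-factor scale
with the Kass–Raftery bands (<2 weak, 2–6 positive, 6–10 strong, >10
very strong; lower bounds inclusive). Marginal likelihoods use
stepping-stone sampling (power posteriors at
$\beta_k = (k/K)^{1/0.3}$, default 10 rungs) — the one deliberate
departure from older practice, because the harmonic-mean estimator is
notoriously unstable; the harmonic option is retained for comparison
with legacy analyses.

## Synthetic data: what it emulates, what it does not

The generators reproduce the statistical structure each stage assumes:
a pure-birth "true" tree with an outgroup attached below the ingroup
root; replicate trees with log-normal branch jitter and
nearest-neighbour-interchange moves applied only adjacent to the ingroup
root, so topological uncertainty concentrates in the deepest clades
(frequencies around 0.7–1.0, as in empirical posteriors); Mk,
threshold-Brownian, shuffled and autologistic traits with recorded
ground truth; and society metadata whose subfamily clusters overlap
partially with geography. Default shapes mirror a realistic study (50
taxa, 8 subfamilies, continental extent, 1000 trees), scaled down in
tests — the test-suite typically runs 10–64 taxa, 10–60 trees, and
hundreds of simulated traits, sizes chosen so the whole suite exercises
every code path at desk scale.

What passing tests on synthetic data do **not** show: the generators make
no attempt at realistic linguistic diversification (no rate variation
across lineages or traits, no geography-aware branching), societies'
locations are Gaussian clusters rather than real settlement patterns, and
trait loss/gain is homogeneous. Conclusions about real folktale corpora
additionally depend on the coding of the trait matrix itself, which the
package consumes as given.

## Numerical choices and degenerate inputs

* Pruning and the up–down pass renormalise per node and track log scale
  factors; zero-length branches and rate 0 are exact limits (identity
  transitions).
* The consensus builder keeps exactly the clades with frequency strictly
  above the threshold (≥ 0.5 required), so retained clades are pairwise
  compatible by counting; ties at exactly 50% are excluded, producing
  polytomies rather than arbitrary resolutions.
* Constant traits: D undefined (flagged, excluded), autologistic fit
  refuses, Mk fits drive rates to the lower bound.
* Gibbs updates use a fixed ascending node order; all stochastic code is
  reproducible under a single integer seed, with per-trait seeds derived
  from it.
* Sliding-window reflection uses a closed-form fold, so degenerate
  (near-point) prior ranges remain valid inputs.

## Known limitations

* Signal, autologistic and ASR stages assume the binary coding is
  meaningful and complete; systematic under-recording in some societies
  will masquerade as absence.
* The D screen follows standard practice in testing each trait at fixed
  $\alpha$ with no multiplicity correction (an FDR column is emitted for
  reference but not used in the headline filter).
* Single-field autologistic inference is information-poor (see stage 2);
  the +/−/0 table should be read with its interval level in mind.
* The "vertical transmission dominant" rule used to select traits for
  ancestral reconstruction — $\lambda$ classified `+` and ($\theta$ not
  `+` or $\hat\lambda > \hat\theta$) — is one reasonable operationalisation
  of "vertical more important than horizontal"; it is deliberately
  surfaced as a documented, replaceable filter rather than buried.
* Mk models assume homogeneous rates across branches and no correlation
  between traits.
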