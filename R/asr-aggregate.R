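#' Aggregate ancestral-state reconstructions over a tree sample
#'
#' For one trait: refits the Mk model (with likelihood-ratio model
#' selection) on every tree of the posterior sample, computes marginal
#' node probabilities, and summarises each consensus clade by the mean
#' `P(present)` over exactly those trees in which the clade occurs,
#' multiplied by the clade's posterior frequency in the sample. The
#' product discounts a reconstruction by the support for the ancestor
#' itself, so `combined <= min(mean_p_present, clade_pp)`.
#'
#' @param sample a `multiPhylo` tree sample (trees should include the
#'   outgroup used to build the consensus).
#' @param states binary/missing tip states named by tip label; code the
#'   outgroup missing so it cannot bias the reconstruction.
#' @param consensus a [majority_consensus()] result defining the clades to
#'   report (ingroup tip sets), or a list of named taxon sets.
#' @param alpha size of the Mk2-vs-Mk1 likelihood-ratio test per tree.
#' @param root_prior `"equal"` or `"stationary"`.
#' @param outgroup optional outgroup label used to root each sample tree
#'   before locating clades (defaults to the consensus outgroup).
#' @return data frame per clade: clade id, members, size, n_trees (trees
#'   containing the clade), mean_p_present, clade_pp, combined, and the
#'   fraction of per-tree fits selecting Mk2.
#' @export
aggregate_over_sample <- function(sample, states, consensus, alpha = 0.05,
                                  root_prior = "equal", outgroup = NULL) {
  validate_tree_sample(sample)
  if (inherits(consensus, "consensus_tree")) {
    outgroup <- outgroup %||% consensus$outgroup
    cl <- consensus$clades
    clades <- setNames(strsplit(cl$clade, ";", fixed = TRUE),
                       sprintf("clade_%02d", seq_len(nrow(cl))))
  } else {
    clades <- consensus
    if (is.null(names(clades)))
      names(clades) <- sprintf("clade_%02d", seq_along(clades))
  }
  clades <- clades[lengths(clades) >= 2]
  n_trees <- length(sample)
  hits <- matrix(NA_real_, length(clades), n_trees,
                 dimnames = list(names(clades), NULL))
  mk2 <- logical(n_trees)
  for (i in seq_len(n_trees)) {
    tr <- sample[[i]]
    if (!is.null(outgroup)) tr <- root_with_outgroup(tr, outgroup)
    model <- fit_and_select(tr, states, alpha = alpha, root_prior = root_prior)
    mk2[i] <- model$kind == "Mk2"
    probs <- marginal_node_probs(tr, states, model, root_prior = root_prior)
    sets <- node_tip_sets(tr)
    for (ci in seq_along(clades)) {
      taxa <- clades[[ci]]
      if (!all(taxa %in% tr$tip.label)) next
      mrca <- if (length(taxa) == ape::Ntip(tr)) info_root(tr)
              else ape::getMRCA(tr, taxa)
      if (is.null(mrca)) next
      desc <- sets[[mrca]]
      if (length(desc) == length(taxa) && setequal(desc, taxa))
        hits[ci, i] <- probs[[as.character(mrca)]]
    }
  }
  n_with <- rowSums(!is.na(hits))
  mean_p <- rowMeans(hits, na.rm = TRUE)
  mean_p[n_with == 0] <- NA_real_
  clade_pp <- n_with / n_trees
  data.frame(clade = names(clades),
             members = vapply(clades, paste, character(1), collapse = ";"),
             size = lengths(clades), n_trees = n_with,
             mean_p_present = unname(mean_p), clade_pp = unname(clade_pp),
             combined = unname(mean_p * clade_pp),
             prop_mk2 = mean(mk2), row.names = NULL, stringsAsFactors = FALSE)
}

info_root <- function(tree) ape::Ntip(tree) + 1L

#' Ancestral corpora at reporting thresholds
#'
#' Collects, per ancestral node, the traits whose combined reconstruction
#' probability exceeds 50% ("inferred") and those at or above 70%
#' ("securely reconstructed"; the upper boundary is inclusive, the lower
#' strict).
#'
#' @param results data frame with columns `trait`, `clade` and `combined`
#'   (rows of [aggregate_over_sample()] stacked over traits, with a
#'   `trait` column added).
#' @param thresholds named numeric: `inferred` (strict lower bound) and
#'   `secure` (inclusive lower bound).
#' @return data frame per clade x trait with logical `inferred` and
#'   `secure` columns; attribute `corpora` holds the per-clade trait lists.
#' @export
ancestral_corpora <- function(results, thresholds = c(inferred = 0.5, secure = 0.7)) {
  stopifnot(all(c("trait", "clade", "combined") %in% names(results)))
  out <- results[, c("trait", "clade", "combined")]
  out$inferred <- !is.na(out$combined) & out$combined > thresholds[["inferred"]]
  out$secure <- !is.na(out$combined) & out$combined >= thresholds[["secure"]]
  corp <- lapply(split(out, out$clade), function(d)
    list(inferred = d$trait[d$inferred], secure = d$trait[d$secure]))
  attr(out, "corpora") <- corp
  out
}
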