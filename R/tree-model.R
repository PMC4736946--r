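#' Read a posterior sample of trees
#'
#' Reads rooted, time-calibrated trees from a Newick or NEXUS file and
#' validates them as a tree sample: every tree must carry the same tip
#' label set, so that clade frequencies across the sample are well defined.
#' NEXUS translate tables are resolved by [ape::read.nexus()].
#'
#' @param path path to a tree file.
#' @param format `"auto"` (guess from content), `"newick"` or `"nexus"`.
#' @return an object of class `multiPhylo`, validated by
#'   [validate_tree_sample()].
#' @export
read_tree_sample <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  trees <- tryCatch(
    suppressWarnings(
      if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (is.null(trees)) stop("failed to parse ", format, " file '", path, "'")
  if (inherits(trees, "phylo")) trees <- c(trees)
  class(trees) <- "multiPhylo"
  validate_tree_sample(trees)
  trees
}

#' Write a tree sample as Newick
#'
#' @param trees a `phylo` or `multiPhylo` object.
#' @param path output file path, one Newick string per line.
#' @export
write_tree_sample <- function(trees, path) {
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Validate a single rooted tree
#'
#' Checks the invariants assumed throughout the pipeline: a single root,
#' unique tip labels, non-negative branch lengths and no degree-2
#' (single-child) internal nodes.
#'
#' @param tree a `phylo` object.
#' @return `tree`, invisibly; errors describe the violated invariant.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths present")
  n <- ape::Ntip(tree)
  # children per internal node
  tab <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  internal <- seq.int(n + 1L, n + tree$Nnode)
  if (any(tab[internal] < 2L))
    stop("internal node(s) with fewer than 2 children (degree-2 nodes)")
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(unique(roots)) != 1L) stop("tree does not have exactly one root")
  invisible(tree)
}

#' Validate a tree sample
#'
#' @param trees a `multiPhylo` object.
#' @return `trees`, invisibly.
#' @export
validate_tree_sample <- function(trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) < 1L) stop("tree sample is empty")
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    validate_tree(trees[[i]])
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop("tree ", i, " has a different taxon set from tree 1")
  }
  invisible(trees)
}

root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' not in tree")
  if (ape::is.rooted(tree)) {
    # already rooted on the outgroup edge?
    kids <- tree$edge[tree$edge[, 1] == ape::Ntip(tree) + 1L, 2]
    og <- match(outgroup, tree$tip.label)
    if (og %in% kids) return(tree)
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Prune a tree to a taxon set and root it on an outgroup
#'
#' Drops all tips outside `keep_taxa` plus the outgroup, suppressing the
#' resulting degree-2 nodes (their branch lengths are summed, so path
#' lengths between retained tips are preserved), then roots the tree on the
#' outgroup edge. The outgroup is always retained even when absent from
#' `keep_taxa` (it may lack trait data but anchors the root).
#'
#' @param tree a `phylo` object.
#' @param keep_taxa character vector of tip labels to retain.
#' @param outgroup single tip label used to root the pruned tree.
#' @return a rooted `phylo` object with tips `keep_taxa` plus `outgroup`.
#' @export
prune_and_root <- function(tree, keep_taxa, outgroup) {
  if (length(keep_taxa) == 0L) stop("keep_taxa is empty")
  keep <- union(keep_taxa, outgroup)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  pruned <- if (length(keep) < ape::Ntip(tree)) ape::keep.tip(tree, keep) else tree
  out <- root_with_outgroup(pruned, outgroup)
  validate_tree(out)
  out
}

# descendant tip-label sets for every node (index 1..Ntip+Nnode)
node_tip_sets <- function(tree) {
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", m)
  sets[seq_len(n)] <- as.list(tree$tip.label)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

clade_key <- function(labels) paste(sort(labels), collapse = "\r")

# per-tree tally of ingroup clades (tip-label sets not containing the
# outgroup) with the subtending branch length of each
ingroup_clades <- function(tree, outgroup) {
  n <- ape::Ntip(tree)
  sets <- node_tip_sets(tree)
  parent_edge_len <- rep(NA_real_, n + tree$Nnode)
  if (!is.null(tree$edge.length))
    parent_edge_len[tree$edge[, 2]] <- tree$edge.length
  internal <- seq.int(n + 1L, n + tree$Nnode)
  keep <- vapply(internal, function(v) !(outgroup %in% sets[[v]]), logical(1))
  nodes <- internal[keep]
  list(keys = vapply(nodes, function(v) clade_key(sets[[v]]), character(1)),
       sizes = vapply(nodes, function(v) length(sets[[v]]), integer(1)),
       brlen = parent_edge_len[nodes],
       sets = sets[nodes])
}

#' Majority-rules consensus with clade posterior frequencies
#'
#' Roots every tree on the outgroup, counts each ingroup clade (the set of
#' ingroup tips descending from an internal node) across the sample, and
#' keeps exactly the clades whose frequency is strictly greater than
#' `threshold`. Because `threshold >= 0.5`, retained clades are pairwise
#' compatible and nest into a single (possibly multifurcating) tree. Clade
#' identity is the ingroup tip set, so the frequency attached to a node is
#' its posterior probability in the sample. Consensus branch lengths are
#' summarised (mean by default) over the trees containing the clade.
#'
#' @param sample a validated `multiPhylo` tree sample.
#' @param threshold minimum clade frequency, strict; must be in `[0.5, 1)`.
#' @param outgroup tip label used to root and orient every tree.
#' @param brlen `"mean"` or `"median"` summary for consensus branch lengths.
#' @return an object of class `consensus_tree`: a list with elements
#'   `tree` (a `phylo` whose node labels are the clade frequencies),
#'   `clades` (data frame: clade members, frequency, branch length),
#'   `outgroup`, `threshold` and `n_trees`.
#' @export
majority_consensus <- function(sample, threshold = 0.5, outgroup,
                               brlen = c("mean", "median")) {
  brlen <- match.arg(brlen)
  validate_tree_sample(sample)
  if (threshold < 0.5)
    stop("threshold below 0.5 would allow incompatible clades")
  if (threshold >= 1) stop("threshold must be < 1")
  rooted <- lapply(sample, root_with_outgroup, outgroup = outgroup)
  n_trees <- length(rooted)
  counts <- list(); lens <- list()
  tip_lens <- NULL
  for (tr in rooted) {
    cl <- ingroup_clades(tr, outgroup)
    for (j in seq_along(cl$keys)) {
      k <- cl$keys[j]
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      lens[[k]] <- c(lens[[k]], cl$brlen[j])
    }
    term <- setNames(tr$edge.length[match(seq_len(ape::Ntip(tr)), tr$edge[, 2])],
                     tr$tip.label)
    tip_lens <- rbind(tip_lens, term[sort(names(term))])
  }
  summ <- if (brlen == "mean") function(x) mean(x, na.rm = TRUE) else
    function(x) median(x, na.rm = TRUE)
  freq <- vapply(counts, function(x) x / n_trees, numeric(1))
  keep <- names(freq)[freq > threshold]
  ingroup <- sort(setdiff(sample[[1]]$tip.label, outgroup))
  # ensure the full ingroup clade is present (frequency = monophyly rate;
  # 1 whenever rooting on the outgroup succeeds in every tree)
  root_key <- clade_key(ingroup)
  if (!root_key %in% keep) keep <- c(keep, root_key)
  freq[root_key] <- freq[root_key] %||% 1
  clade_sets <- lapply(keep, function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
  clade_len <- vapply(keep, function(k) {
    if (is.null(lens[[k]])) NA_real_ else summ(lens[[k]])
  }, numeric(1))
  mean_tip_len <- apply(tip_lens, 2, summ)

  fmt <- function(x) formatC(x, format = "g", digits = 10)
  build <- function(set, idx) {
    # idx: indices of clades strictly inside `set`
    maximal <- idx
    if (length(idx) > 1) {
      sizes <- lengths(clade_sets[idx])
      maximal <- idx[vapply(seq_along(idx), function(a) {
        !any(vapply(seq_along(idx), function(b) {
          b != a && sizes[b] > sizes[a] &&
            all(clade_sets[[idx[a]]] %in% clade_sets[[idx[b]]])
        }, logical(1)))
      }, logical(1))]
    }
    covered <- unlist(clade_sets[maximal])
    parts <- character(0)
    for (m in maximal) {
      inner <- setdiff(idx, m)
      inner <- inner[vapply(inner, function(b)
        all(clade_sets[[b]] %in% clade_sets[[m]]), logical(1))]
      len <- clade_len[m]
      parts <- c(parts, paste0("(", build(clade_sets[[m]], inner), ")",
                               fmt(freq[keep[m]]),
                               if (!is.na(len)) paste0(":", fmt(len))))
    }
    singles <- setdiff(set, covered)
    parts <- c(parts, paste0(singles, ":", fmt(mean_tip_len[singles])))
    paste(parts, collapse = ",")
  }
  root_idx <- match(root_key, keep)
  inner_idx <- setdiff(seq_along(keep), root_idx)
  og_len <- mean_tip_len[outgroup]
  in_len <- clade_len[root_idx]
  nwk <- paste0("((", build(ingroup, inner_idx), ")", fmt(freq[root_key]),
                if (!is.na(in_len)) paste0(":", fmt(in_len)),
                ",", outgroup, ":", fmt(og_len), ")1;")
  tree <- ape::read.tree(text = nwk)
  clades_df <- data.frame(
    clade = vapply(clade_sets, function(s) paste(sort(s), collapse = ";"), character(1)),
    size = lengths(clade_sets),
    frequency = unname(freq[keep]),
    branch_length = unname(clade_len),
    stringsAsFactors = FALSE)
  structure(list(tree = tree, clades = clades_df, outgroup = outgroup,
                 threshold = threshold, n_trees = n_trees),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat("Majority-rules consensus of", x$n_trees, "trees",
      sprintf("(threshold > %.2f, outgroup %s)\n", x$threshold, x$outgroup))
  cat(" ", nrow(x$clades), "ingroup clades; frequencies",
      sprintf("%.2f-%.2f\n", min(x$clades$frequency), max(x$clades$frequency)))
  invisible(x)
}

#' Write a consensus tree as annotated Newick
#'
#' Node labels carry the clade posterior frequencies.
#'
#' @param con a `consensus_tree`.
#' @param path output path.
#' @export
write_consensus <- function(con, path) {
  ape::write.tree(con$tree, file = path)
  invisible(path)
}

#' Frequency of a clade in a tree sample
#'
#' The fraction of trees (rooted on the outgroup if given) in which
#' `taxon_set` is monophyletic, i.e. forms exactly the tip set of some node.
#' This is the clade's posterior probability when the sample is a Bayesian
#' posterior.
#'
#' @param sample a `multiPhylo` tree sample.
#' @param taxon_set character vector of at least two tip labels.
#' @param outgroup optional tip label to root each tree before testing.
#' @return a proportion in `[0, 1]`.
#' @export
clade_frequency <- function(sample, taxon_set, outgroup = NULL) {
  validate_tree_sample(sample)
  taxon_set <- unique(taxon_set)
  if (length(taxon_set) < 2L) stop("taxon_set must contain at least 2 taxa")
  missing <- setdiff(taxon_set, sample[[1]]$tip.label)
  if (length(missing)) stop("taxa not in sample: ", paste(missing, collapse = ", "))
  hits <- vapply(sample, function(tr) {
    if (!is.null(outgroup)) tr <- root_with_outgroup(tr, outgroup)
    is_clade(tr, taxon_set)
  }, logical(1))
  mean(hits)
}

# monophyly of a label set on a rooted tree
is_clade <- function(tree, taxa) {
  tips <- match(taxa, tree$tip.label)
  if (anyNA(tips)) return(FALSE)
  if (length(tips) == ape::Ntip(tree)) return(TRUE)
  mrca <- ape::getMRCA(tree, tips)
  if (is.null(mrca)) return(FALSE)
  desc <- node_tip_sets(tree)[[mrca]]
  length(desc) == length(taxa) && setequal(desc, taxa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
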