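# Shared traversal scaffolding: children lists, postorder node sequence and
# per-node subtending branch lengths, computed once per tree and reused by
# the D statistic, the pruning likelihood and the simulators.
postorder_info <- function(tree) {
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  children <- vector("list", m)
  for (k in seq_len(nrow(tr$edge)))
    children[[tr$edge[k, 1]]] <- c(children[[tr$edge[k, 1]]], tr$edge[k, 2])
  elen <- rep(NA_real_, m)
  if (!is.null(tr$edge.length)) elen[tr$edge[, 2]] <- tr$edge.length
  # internal nodes in the order their last child edge appears = postorder
  post_nodes <- unique(tr$edge[, 1])
  root <- n + 1L
  list(n_tip = n, n_node = m, root = root, children = children,
       edge_len = elen, post_nodes = post_nodes,
       pre_edges = tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE],
       tip_labels = tree$tip.label)
}

# match a named state vector onto tree tips, erroring on gaps;
# coercion preserves names
match_tip_states <- function(tree, states, allow_missing = FALSE,
                             mode = "integer") {
  states <- setNames(as.vector(states, mode = mode), names(states))
  if (is.null(names(states))) {
    if (length(states) != ape::Ntip(tree))
      stop("states must be named by tip label or match the number of tips")
    names(states) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing))
    stop("tip(s) without a state: ", paste(missing, collapse = ", "))
  out <- states[tree$tip.label]
  if (!allow_missing && anyNA(out))
    stop("missing state for tip(s): ",
         paste(tree$tip.label[is.na(out)], collapse = ", "))
  out
}
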