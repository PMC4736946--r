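#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    stop("longitude out of [-180, 180]")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

new_neighbor_graph <- function(nodes, edges, kind, radius_km = NA_real_) {
  if (anyDuplicated(nodes)) stop("duplicate society labels")
  if (nrow(edges)) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, c(2, 1)]
    edges <- unique(edges)
    if (any(edges[, 1] == edges[, 2])) stop("self-loop in edge set")
  }
  structure(list(nodes = nodes, edges = edges, kind = kind,
                 radius_km = radius_km),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("%s neighbour graph: %d societies, %d edges, mean degree %.2f%s\n",
              x$kind, length(x$nodes), nrow(x$edges), mean_degree(x),
              if (!is.na(x$radius_km)) sprintf(" (radius %g km)", x$radius_km) else ""))
  invisible(x)
}

#' Mean degree of a neighbour graph
#' @param g a `neighbor_graph`.
#' @return `2 * n_edges / n_nodes`.
#' @export
mean_degree <- function(g) 2 * nrow(g$edges) / length(g$nodes)

#' Build the spatial neighbour graph
#'
#' Two societies are spatial neighbours iff their great-circle distance is
#' at most `radius_km` (boundary inclusive). Societies without coordinates
#' (e.g. dispersed groups that cannot be tied to one location) must be
#' excluded beforehand.
#'
#' @param meta a `society_metadata` data frame with complete coordinates.
#' @param radius_km neighbourhood radius in km.
#' @return a `neighbor_graph` of kind `"spatial"`.
#' @export
build_spatial_graph <- function(meta, radius_km = 1000) {
  if (nrow(meta) < 2L) stop("need at least 2 societies")
  if (anyNA(meta$lat) || anyNA(meta$lon))
    stop("societies without coordinates must be excluded first: ",
         paste(meta$society[is.na(meta$lat) | is.na(meta$lon)], collapse = ", "))
  idx <- which(upper.tri(matrix(0, nrow(meta), nrow(meta))), arr.ind = TRUE)
  d <- haversine_km(meta$lat[idx[, 1]], meta$lon[idx[, 1]],
                    meta$lat[idx[, 2]], meta$lon[idx[, 2]])
  hit <- d <= radius_km
  edges <- cbind(meta$society[idx[hit, 1]], meta$society[idx[hit, 2]])
  new_neighbor_graph(meta$society, edges, "spatial", radius_km)
}

#' Build the phylogenetic (linguistic) neighbour graph
#'
#' Two societies are phylogenetic neighbours iff they belong to the same
#' linguistic subfamily. Societies with subfamily `"none"` are isolated.
#'
#' @param meta a `society_metadata` data frame.
#' @return a `neighbor_graph` of kind `"phylogenetic"`.
#' @export
build_phylo_graph <- function(meta) {
  edges <- matrix(character(0), 0, 2)
  for (sf in setdiff(unique(meta$subfamily), "none")) {
    members <- sort(meta$society[meta$subfamily == sf])
    if (length(members) > 1L)
      edges <- rbind(edges, t(utils::combn(members, 2)))
  }
  new_neighbor_graph(meta$society, edges, "phylogenetic")
}

edge_keys <- function(g) {
  if (!nrow(g$edges)) return(character(0))
  paste(g$edges[, 1], g$edges[, 2], sep = "\r")
}

#' Compare two neighbour graphs on the same societies
#'
#' Reports each graph's mean degree and the overlap of their edge sets:
#' pairs of societies that are neighbours in both graphs and pairs unique
#' to each. By construction the degree-sum identity
#' `mean_degree * n = 2 * (shared + unique)` holds for each graph.
#'
#' @param gA,gB `neighbor_graph` objects sharing a node set.
#' @return list: `mean_degree_a`, `mean_degree_b`, `shared`, `unique_a`,
#'   `unique_b`, `n`.
#' @export
graph_summary <- function(gA, gB) {
  if (!setequal(gA$nodes, gB$nodes)) stop("graphs have different node sets")
  ka <- edge_keys(gA); kb <- edge_keys(gB)
  shared <- length(intersect(ka, kb))
  list(mean_degree_a = mean_degree(gA), mean_degree_b = mean_degree(gB),
       shared = shared, unique_a = length(ka) - shared,
       unique_b = length(kb) - shared, n = length(gA$nodes))
}

#' Write a neighbour graph as a TSV edge list
#' @param g a `neighbor_graph`.
#' @param path output path.
#' @export
write_graph <- function(g, path) {
  write.table(data.frame(from = g$edges[, 1], to = g$edges[, 2]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 0-based adjacency lists in a fixed node order (ascending labels)
adjacency_lists <- function(g, nodes) {
  adj <- rep(list(integer(0)), length(nodes))
  if (nrow(g$edges)) {
    i <- match(g$edges[, 1], nodes); j <- match(g$edges[, 2], nodes)
    if (anyNA(i) || anyNA(j)) stop("graph edge references unknown node")
    for (k in seq_along(i)) {
      adj[[i[k]]] <- c(adj[[i[k]]], j[k] - 1L)
      adj[[j[k]]] <- c(adj[[j[k]]], i[k] - 1L)
    }
  }
  adj
}
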