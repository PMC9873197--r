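#' Per-node graphlet orbit counts
#'
#' Counts, for every node, how often it participates in each automorphism
#' orbit of the connected graphlets on up to four nodes, on the unweighted
#' topology of the network (an edge wherever the adjacency is nonzero).
#' The 11 non-redundant orbits used by the graphlet correlation distance
#' are orbits {0, 1, 2, 4, 5, 6, 7, 8, 9, 10, 11} of the standard 0-14
#' enumeration; orbit 0 equals the node degree.
#'
#' @param adj adjacency matrix (any nonzero entry is an edge).
#' @param all_orbits if TRUE return all 15 orbits instead of the
#'   non-redundant 11.
#' @return integer matrix, nodes x orbits, with orbit names as columns.
#' @export
orbit_counts <- function(adj, all_orbits = FALSE) {
  a <- matrix(as.integer(adj != 0), nrow(adj))
  diag(a) <- 0L
  counts <- orbit_counts_cpp(a)
  colnames(counts) <- paste0("O", 0:14)
  rownames(counts) <- rownames(adj)
  if (all_orbits) counts else counts[, paste0("O", c(0:2, 4:11)), drop = FALSE]
}

# Spearman correlation matrix of the 11 orbit-count columns; one synthetic
# all-ones signature row is appended so that constant orbit columns (e.g.
# in very sparse networks) still yield defined correlations.
graphlet_correlation_matrix <- function(adj) {
  oc <- orbit_counts(adj)
  oc <- rbind(oc, rep(1L, ncol(oc)))
  g <- suppressWarnings(stats::cor(oc, method = "spearman"))
  # a column can still be constant (e.g. every node with orbit count 1 in a
  # degree-regular graph); its undefined correlations are set to 0
  g[is.na(g)] <- 0
  diag(g) <- 1
  g
}

#' Graphlet correlation distance between two networks
#'
#' Per network, the Spearman correlation matrix among the 11 non-redundant
#' orbit-count columns (across nodes) is computed; the GCD is the Euclidean
#' distance between the strict upper triangles (55 entries) of the two
#' correlation matrices.  Symmetric, and 0 for isomorphic networks.
#'
#' @param net1,net2 adjacency matrices (at least 2 nodes each).
#' @return nonnegative distance.
#' @export
graphlet_correlation_distance <- function(net1, net2) {
  if (nrow(net1) < 2L || nrow(net2) < 2L) stop("networks need at least 2 nodes")
  g1 <- graphlet_correlation_matrix(net1)
  g2 <- graphlet_correlation_matrix(net2)
  ut <- upper.tri(g1)
  sqrt(sum((g1[ut] - g2[ut])^2))
}
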