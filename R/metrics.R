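#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected Rand index computed from the contingency
#' table.  Both label vectors must cover the same items (matched by name
#' when both are named).
#'
#' @param p1,p2 label vectors.
#' @return ARI in [-1, 1]; 1 iff the partitions are identical up to label
#'   permutation.
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("partitions cover different item sets")
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) stop("partitions cover different item sets")
    p2 <- p2[names(p1)]
  }
  tab <- table(p1, p2)
  n <- length(p1)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  nc2 <- choose(n, 2)
  expected <- a * b / nc2
  maxindex <- (a + b) / 2
  denom <- maxindex - expected
  if (abs(denom) < 1e-12) {
    # both partitions trivial (all-singleton or all-in-one on both sides)
    return(if (sum_ij == maxindex) 1 else 0)
  }
  (sum_ij - expected) / denom
}

#' Average silhouette width of a partition
#'
#' Mean over items of (b - a) / max(a, b), where a is the mean
#' dissimilarity to the item's own cluster and b the smallest mean
#' dissimilarity to another cluster.  Items in singleton clusters
#' contribute silhouette 0.  Undefined (error) for k = 1.
#'
#' @param labels cluster labels.
#' @param D dissimilarity matrix in the same item order.
#' @return ASW in [-1, 1].
#' @export
average_silhouette_width <- function(labels, D) {
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  if (k < 2L) stop("ASW undefined for a single cluster")
  n <- length(labels)
  if (nrow(D) != n) stop("dissimilarity matrix does not match labels")
  sil <- numeric(n)
  sizes <- tabulate(labels)
  for (i in seq_len(n)) {
    ci <- labels[i]
    if (sizes[ci] == 1L) { sil[i] <- 0; next }
    a <- sum(D[i, labels == ci]) / (sizes[ci] - 1L)
    b <- min(vapply(setdiff(seq_len(k), ci),
                    function(c) mean(D[i, labels == c]), numeric(1)))
    sil[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(sil)
}

#' Normalized centralities on the largest connected component
#'
#' Degree, betweenness and closeness centrality, normalized to [0, 1], are
#' computed on the largest connected component (LCC) of the network's
#' unweighted topology; nodes outside the LCC get all three centralities 0.
#' Ties between equal-sized components are broken towards the component
#' containing the smallest node index.  Degree is divided by (n_lcc - 1),
#' betweenness by (n_lcc - 1)(n_lcc - 2)/2, and closeness is
#' (n_lcc - 1) / sum of shortest-path lengths.
#'
#' @param adj adjacency matrix in [0, 1].
#' @return data.frame with columns node, degree, betweenness, closeness,
#'   in_lcc.
#' @export
centralities <- function(adj) {
  n <- nrow(adj)
  ids <- rownames(adj) %||% as.character(seq_len(n))
  out <- data.frame(node = ids, degree = numeric(n), betweenness = numeric(n),
                    closeness = numeric(n), in_lcc = logical(n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
  comp <- igraph::components(g)
  if (max(comp$csize) < 2L) return(out)
  biggest <- which(comp$csize == max(comp$csize))
  # smallest node index among maximal components
  first_member <- vapply(biggest, function(c) min(which(comp$membership == c)), integer(1))
  lcc <- biggest[which.min(first_member)]
  members <- which(comp$membership == lcc)
  sub <- igraph::induced_subgraph(g, members)
  nl <- length(members)
  deg <- igraph::degree(sub) / (nl - 1)
  btw <- if (nl > 2) igraph::betweenness(sub, normalized = TRUE) else rep(0, nl)
  cls <- igraph::closeness(sub, normalized = TRUE)
  out$degree[members] <- deg
  out$betweenness[members] <- btw
  out$closeness[members] <- cls
  out$in_lcc[members] <- TRUE
  out
}

#' Detect hub nodes
#'
#' Hubs are the nodes strictly above the empirical `quantile` (default 95%)
#' of all three centralities (degree, betweenness, closeness)
#' simultaneously.  The quantile uses the inclusive linear-interpolation
#' definition; an empty hub set is a legitimate outcome.
#'
#' @param adj adjacency matrix, or a centrality table from [centralities()].
#' @param quantile empirical quantile, default 0.95.
#' @return list with `hubs` (character IDs), `cutoffs`, and the centrality
#'   table.
#' @export
detect_hubs <- function(adj, quantile = 0.95) {
  stopifnot(quantile > 0, quantile < 1)
  ct <- if (is.data.frame(adj)) adj else centralities(adj)
  if (nrow(ct) == 0L)
    return(list(hubs = character(0), cutoffs = c(degree = NA, betweenness = NA, closeness = NA),
                centralities = ct))
  cut <- vapply(c("degree", "betweenness", "closeness"),
                function(m) stats::quantile(ct[[m]], quantile, type = 7, names = FALSE),
                numeric(1))
  is_hub <- ct$degree > cut["degree"] & ct$betweenness > cut["betweenness"] &
    ct$closeness > cut["closeness"]
  list(hubs = ct$node[is_hub], cutoffs = cut, centralities = ct)
}

#' Rank tied hub sets by mean centrality
#'
#' Among candidates sharing the maximal hub count, each candidate's hubs
#' are averaged per centrality measure; candidates are ranked per measure
#' (average ranks on ties, higher mean = higher rank) and the candidate
#' with the highest mean rank across the three measures wins.  Residual
#' ties go to the first candidate in enumeration order.
#'
#' @param candidates list of results from [detect_hubs()] (each carrying
#'   `hubs` and `centralities`).
#' @return index of the selected candidate.
#' @export
rank_hub_sets <- function(candidates) {
  if (!length(candidates)) stop("empty candidate list")
  if (length(candidates) == 1L) return(1L)
  means <- t(vapply(candidates, function(cand) {
    ct <- cand$centralities
    sel <- ct$node %in% cand$hubs
    if (!any(sel)) return(c(degree = 0, betweenness = 0, closeness = 0))
    c(degree = mean(ct$degree[sel]),
      betweenness = mean(ct$betweenness[sel]),
      closeness = mean(ct$closeness[sel]))
  }, numeric(3)))
  ranks <- apply(means, 2L, rank)        # average ranks on ties
  mean_rank <- rowMeans(ranks)
  which.max(mean_rank)                   # first on residual ties
}

#' Jaccard index between two sets
#'
#' |H1 intersect H2| / |H1 union H2|; two empty sets count as identical
#' (index 1).
#'
#' @param h1,h2 vectors interpreted as sets.
#' @return value in [0, 1].
#' @export
jaccard_index <- function(h1, h2) {
  u <- union(h1, h2)
  if (!length(u)) return(1)
  length(intersect(h1, h2)) / length(u)
}

#' Cosine similarity between hub sets at the family level
#'
#' Hub genera are mapped to families; the two family frequency vectors over
#' the families present in the union of the hub sets are compared with the
#' cosine similarity.  Undefined (NA) when either hub set is empty.
#'
#' @param h1,h2 character vectors of hub genus IDs.
#' @param taxonomy data.frame with columns taxon_id (or genus) and family.
#' @return value in [0, 1], or NA if a hub set is empty.
#' @export
family_cosine_similarity <- function(h1, h2, taxonomy) {
  if (!length(h1) || !length(h2)) return(NA_real_)
  key <- if ("taxon_id" %in% names(taxonomy)) taxonomy$taxon_id else taxonomy$genus
  fam <- stats::setNames(as.character(taxonomy$family), key)
  f1 <- fam[h1]; f2 <- fam[h2]
  if (anyNA(f1) || anyNA(f2)) stop("hub IDs missing from taxonomy")
  fams <- union(f1, f2)
  v1 <- as.numeric(table(factor(f1, levels = fams)))
  v2 <- as.numeric(table(factor(f2, levels = fams)))
  sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
}
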