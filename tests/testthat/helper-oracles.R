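# Brute-force oracles and small fixture builders shared across tests.

# Independent per-node orbit counter: enumerate every 3- and 4-subset,
# classify the induced subgraph through igraph isomorphism against
# reference graphlets, and assign orbits by within-subset degree (which is
# orbit-determining for graphlets on <= 4 nodes).
oracle_orbit_counts <- function(adj) {
  n <- nrow(adj)
  orb <- matrix(0L, n, 15)
  ref3 <- list(path = igraph::make_graph(c(1, 2, 2, 3), directed = FALSE),
               tri = igraph::make_full_graph(3))
  ref4 <- list(p4 = igraph::make_graph(c(1, 2, 2, 3, 3, 4), directed = FALSE),
               star = igraph::make_star(4, mode = "undirected"),
               c4 = igraph::make_ring(4),
               paw = igraph::make_graph(c(1, 2, 2, 3, 3, 1, 1, 4), directed = FALSE),
               diamond = igraph::make_graph(c(1, 2, 2, 3, 3, 1, 1, 4, 2, 4), directed = FALSE),
               k4 = igraph::make_full_graph(4))
  deg_orbit3 <- list(path = c(`1` = 1L, `2` = 2L), tri = c(`2` = 3L))
  deg_orbit4 <- list(p4 = c(`1` = 4L, `2` = 5L), star = c(`1` = 6L, `3` = 7L),
                     c4 = c(`2` = 8L), paw = c(`1` = 9L, `2` = 10L, `3` = 11L),
                     diamond = c(`2` = 12L, `3` = 13L), k4 = c(`3` = 14L))
  classify <- function(nodes, refs, deg_orbits) {
    sub <- adj[nodes, nodes, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub > 0, mode = "undirected")
    if (igraph::components(g)$no > 1L) return()
    for (nm in names(refs)) {
      if (igraph::isomorphic(g, refs[[nm]])) {
        degs <- rowSums(sub > 0)
        omap <- deg_orbits[[nm]]
        for (t in seq_along(nodes))
          orb[nodes[t], omap[[as.character(degs[t])]] + 1L] <<-
            orb[nodes[t], omap[[as.character(degs[t])]] + 1L] + 1L
        return()
      }
    }
  }
  if (n >= 3) apply(utils::combn(n, 3), 2L, classify, refs = ref3, deg_orbits = deg_orbit3)
  if (n >= 4) apply(utils::combn(n, 4), 2L, classify, refs = ref4, deg_orbits = deg_orbit4)
  orb[, 1] <- as.integer(rowSums(adj > 0))
  colnames(orb) <- paste0("O", 0:14)
  rownames(orb) <- rownames(adj)
  orb[, paste0("O", c(0:2, 4:11))]
}

random_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p_edge)
  a <- a + t(a)
  dimnames(a) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  a
}

# ARI by direct enumeration of all item pairs
oracle_ari <- function(l1, l2) {
  n <- length(l1)
  a <- b <- c <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s1 <- l1[i] == l1[j]; s2 <- l2[i] == l2[j]
    if (s1 && s2) a <- a + 1
    else if (s1 && !s2) b <- b + 1
    else if (!s1 && s2) c <- c + 1
    else d <- d + 1
  }
  np <- a + b + c + d
  expected <- (a + b) * (a + c) / np
  maxidx <- ((a + b) + (a + c)) / 2
  if (abs(maxidx - expected) < 1e-12) return(if (b + c == 0) 1 else 0)
  (a - expected) / (maxidx - expected)
}

star_adjacency <- function(n_leaves) {
  n <- n_leaves + 1
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  dimnames(a) <- list(paste0("v", 1:n), paste0("v", 1:n))
  a
}

two_clique_adjacency <- function(size = 5) {
  n <- 2 * size
  a <- matrix(0, n, n)
  a[1:size, 1:size] <- 1
  a[(size + 1):n, (size + 1):n] <- 1
  diag(a) <- 0
  a[size, size + 1] <- a[size + 1, size] <- 1
  dimnames(a) <- list(paste0("v", 1:n), paste0("v", 1:n))
  a
}

# well-separated point clouds as a dissimilarity matrix
blob_dissimilarity <- function(sizes, gap = 10, seed = 1) {
  set.seed(seed)
  centers <- seq_along(sizes) * gap
  x <- as.vector(unlist(mapply(function(c, s) rnorm(s, c, 0.3), centers, sizes)))
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("i", seq_along(x)), paste0("i", seq_along(x)))
  attr(d, "labels") <- rep(seq_along(sizes), sizes)
  d
}

small_counts <- function(p = 8, n = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(p * n, 30) + 1, p, n)
  dimnames(m) <- list(sprintf("t%02d", 1:p), sprintf("s%02d", 1:n))
  storage.mode(m) <- "double"
  m
}
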