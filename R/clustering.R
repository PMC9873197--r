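#' Hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering cut at k clusters; average linkage by default.
#'
#' @param D dissimilarity matrix.
#' @param k number of clusters.
#' @param linkage one of "average", "single", "complete", "ward.D2".
#' @return named integer vector of cluster labels.
#' @export
hierarchical_clustering <- function(D, k, linkage = "average") {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(D)) stop("k exceeds number of items")
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  stats::cutree(hc, k = k)
}

#' Spectral clustering of a similarity matrix
#'
#' Symmetric-normalized Laplacian embedding: rows of the top-k eigenvectors
#' of D^{-1/2} S D^{-1/2} are normalized to unit length and clustered by
#' k-means (25 restarts, fixed seed).  If the similarity graph has more
#' connected components than k, components are labeled directly with a
#' warning.
#'
#' @param S symmetric nonnegative similarity matrix.
#' @param k number of clusters.
#' @param seed RNG seed for k-means.
#' @return named integer vector of cluster labels.
#' @export
spectral_clustering <- function(S, k, seed = 1) {
  if (any(S < 0)) stop("similarity matrix must be nonnegative")
  n <- nrow(S)
  if (k > n) stop("k exceeds number of items")
  A <- S
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > k) {
    warning("similarity graph has ", comp$no, " components > k = ", k,
            "; labeling components directly")
    out <- comp$membership
    names(out) <- rownames(S)
    return(out)
  }
  d <- rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- dinv * t(dinv * A)            # D^{-1/2} A D^{-1/2}
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  nr <- sqrt(rowSums(U^2))
  U[nr > 0, ] <- U[nr > 0, , drop = FALSE] / nr[nr > 0]
  old <- .Random.seed_save()
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = 25, iter.max = 100)
  .Random.seed_restore(old)
  out <- km$cluster
  names(out) <- rownames(S)
  out
}

adjacency_to_igraph <- function(adj, weighted = TRUE) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = if (weighted) TRUE else NULL,
                                           diag = FALSE)
  g
}

#' Fast greedy modularity clustering of a weighted network
#'
#' Determines the number of communities internally.  An empty edge set
#' yields singleton clusters with a warning.
#'
#' @param adj adjacency matrix in [0, 1].
#' @return named integer vector of cluster labels.
#' @export
fast_greedy_modularity <- function(adj) {
  if (nrow(adj) == 0L) stop("empty node set")
  g <- adjacency_to_igraph(adj)
  if (igraph::ecount(g) == 0L) {
    warning("empty edge set; every node its own cluster")
    out <- seq_len(nrow(adj)); names(out) <- rownames(adj)
    return(out)
  }
  cm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  out <- igraph::membership(cm)
  out <- as.integer(out)
  names(out) <- rownames(adj)
  out
}

#' Louvain community detection on a weighted network
#'
#' Multi-level modularity optimization; deterministic under a fixed seed
#' and node order.
#'
#' @param adj adjacency matrix in [0, 1].
#' @param seed RNG seed.
#' @return named integer vector of cluster labels.
#' @export
louvain_clustering <- function(adj, seed = 1) {
  if (nrow(adj) == 0L) stop("empty node set")
  g <- adjacency_to_igraph(adj)
  if (igraph::ecount(g) == 0L) {
    warning("empty edge set; every node its own cluster")
    out <- seq_len(nrow(adj)); names(out) <- rownames(adj)
    return(out)
  }
  old <- .Random.seed_save()
  set.seed(seed)
  cm <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  .Random.seed_restore(old)
  out <- as.integer(igraph::membership(cm))
  names(out) <- rownames(adj)
  out
}

#' Signed-diffusion clustering of a sparsified association matrix
#'
#' A deliberately simple stand-in for flow-based clustering of signed
#' microbial association networks (it is NOT the manta algorithm): the
#' signed sparsified associations are diffused by repeated multiplication
#' with themselves (renormalized each step), nodes are then grouped by
#' average-linkage clustering of the correlation distance between their
#' diffusion profiles, and k is self-selected in 2..k_max by maximizing the
#' average silhouette width of that distance.
#'
#' @param rstar sparsified association matrix (signed, structural zeros).
#' @param steps diffusion steps, default 3.
#' @param k_max largest k tried, default 10.
#' @return named integer vector of cluster labels.
#' @export
signed_diffusion_clustering <- function(rstar, steps = 3, k_max = 10) {
  p <- nrow(rstar)
  W <- rstar
  diag(W) <- 0
  if (all(W == 0)) {
    warning("empty edge set; every node its own cluster")
    out <- seq_len(p); names(out) <- rownames(rstar)
    return(out)
  }
  W <- W / max(abs(W))
  M <- W
  for (s in seq_len(steps - 1L)) {
    M <- M %*% W
    mx <- max(abs(M))
    if (mx > 0) M <- M / mx
  }
  M <- M + t(M)
  sds <- apply(M, 1L, stats::sd)
  cr <- suppressWarnings(stats::cor(t(M)))
  cr[!is.finite(cr)] <- 0
  diag(cr) <- 1
  D <- 0.5 * (1 - cr)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ks <- seq(2L, min(k_max, p - 1L))
  if (length(ks) == 0L) ks <- 2L
  best <- NULL; best_asw <- -Inf
  for (k in ks) {
    lab <- stats::cutree(hc, k = k)
    asw <- tryCatch(average_silhouette_width(lab, D), error = function(e) -Inf)
    if (asw > best_asw + 1e-12) { best_asw <- asw; best <- lab }
  }
  names(best) <- rownames(rstar)
  best
}

#' Partitioning around medoids
#'
#' BUILD + SWAP minimization of total dissimilarity to cluster medoids.
#'
#' @param D dissimilarity matrix.
#' @param k number of clusters.
#' @param seed unused (PAM is deterministic); kept for a uniform interface.
#' @return named integer vector of cluster labels.
#' @export
pam_clustering <- function(D, k, seed = 1) {
  if (k < 1) stop("k must be >= 1")
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
  out <- fit$clustering
  names(out) <- rownames(D)
  out
}

# ---- Dirichlet-multinomial mixture ----------------------------------------

dm_logdens <- function(x_mat, alpha) {
  # x_mat: samples x taxa counts; alpha: taxa vector; returns per-sample
  # Dirichlet-multinomial log density (without the multinomial coefficient,
  # which is constant across components)
  A <- sum(alpha)
  N <- rowSums(x_mat)
  lgamma(A) - lgamma(N + A) +
    rowSums(lgamma(sweep(x_mat, 2L, alpha, "+"))) - sum(lgamma(alpha))
}

fit_dm_component <- function(x_mat, w, alpha0, iter = 8) {
  # Minka fixed-point update of Dirichlet-multinomial parameters with
  # sample weights w
  alpha <- alpha0
  N <- rowSums(x_mat)
  for (it in seq_len(iter)) {
    A <- sum(alpha)
    num <- colSums(w * (digamma(sweep(x_mat, 2L, alpha, "+")) - digamma(alpha)[col(x_mat)]))
    den <- sum(w * (digamma(N + A) - digamma(A)))
    if (den <= 0) break
    alpha_new <- alpha * pmax(num, 1e-12) / den
    alpha_new <- pmin(pmax(alpha_new, 1e-6), 1e6)
    if (max(abs(alpha_new - alpha) / pmax(alpha, 1e-8)) < 1e-6) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  alpha
}

fit_dmm_k <- function(x_mat, k, seed, em_iter = 100, tol = 1e-6) {
  n <- nrow(x_mat); p <- ncol(x_mat)
  fr <- x_mat / pmax(rowSums(x_mat), 1)
  old <- .Random.seed_save()
  set.seed(seed + k)
  init <- if (k == 1L) rep(1L, n) else stats::kmeans(fr, centers = k, nstart = 10)$cluster
  .Random.seed_restore(old)
  alphas <- lapply(seq_len(k), function(c) {
    m <- colMeans(fr[init == c, , drop = FALSE])
    pmax(m, 1e-6) * 50
  })
  pi_k <- as.numeric(table(factor(init, levels = seq_len(k)))) / n
  pi_k <- pmax(pi_k, 1e-8); pi_k <- pi_k / sum(pi_k)
  ll_old <- -Inf; ll_trace <- numeric(0)
  gamma <- matrix(1 / k, n, k)
  for (it in seq_len(em_iter)) {
    ld <- vapply(seq_len(k), function(c) dm_logdens(x_mat, alphas[[c]]), numeric(n))
    ld <- ld + rep(log(pi_k), each = n)
    mx <- apply(ld, 1L, max)
    ll <- sum(mx + log(rowSums(exp(ld - mx))))
    ll_trace <- c(ll_trace, ll)
    gamma <- exp(ld - mx)
    gamma <- gamma / rowSums(gamma)
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll_old)) break
    ll_old <- ll
    pi_k <- pmax(colMeans(gamma), 1e-8); pi_k <- pi_k / sum(pi_k)
    for (c in seq_len(k))
      alphas[[c]] <- fit_dm_component(x_mat, gamma[, c], alphas[[c]])
  }
  list(loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       alphas = alphas, pi = pi_k, gamma = gamma,
       labels = max.col(gamma))
}

# Laplace-approximated log model evidence in its Schwarz form: every free
# parameter (k Dirichlet vectors of length p plus k-1 mixture weights)
# contributes 0.5 log n, i.e. the O(1) terms of the full Laplace integral
# are dropped.  An explicit-Hessian version (expected complete-data
# curvature) proved too erratic for order selection on overdispersed
# counts, so the Schwarz form is used for choosing k.
dmm_evidence <- function(fit, x_mat) {
  n <- nrow(x_mat); k <- length(fit$alphas); p <- ncol(x_mat)
  S <- k * p + (k - 1)
  fit$loglik - 0.5 * S * log(n)
}

#' Dirichlet-multinomial mixture clustering of samples
#'
#' EM fit of k-component Dirichlet-multinomial mixtures for k = 1..k_max
#' applied directly to the count matrix (samples as observations); the
#' number of components is chosen by Laplace-approximated model evidence
#' and samples are assigned to their maximum-responsibility component.
#'
#' @param counts count matrix, taxa x samples.
#' @param k_max largest number of components tried, default 7.
#' @param seed RNG seed (initialization).
#' @return list with `labels` (named integer vector), `k`, `evidence`
#'   (per-k vector) and the selected fit.
#' @export
dmm_fit <- function(counts, k_max = 7, seed = 1) {
  x <- t(counts)  # samples x taxa
  fits <- list(); ev <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    f <- tryCatch(fit_dmm_k(x, k, seed), error = function(e) NULL)
    if (is.null(f)) next
    fits[[k]] <- f
    ev[k] <- dmm_evidence(f, x)
  }
  if (all(is.na(ev))) stop("DMM fit failed for every k")
  kbest <- which.max(ev)
  labels <- fits[[kbest]]$labels
  names(labels) <- colnames(counts)
  list(labels = labels, k = kbest, evidence = ev, fit = fits[[kbest]])
}

#' Choose k by maximizing the average silhouette width
#'
#' Runs PAM or spectral clustering for each k in `k_range` on the given
#' scaled dissimilarity matrix and returns the partition with maximal ASW
#' (ties broken towards the smallest k).
#'
#' @param D scaled dissimilarity matrix.
#' @param algorithm "pam" or "spectral" (spectral uses similarity 1 - D).
#' @param k_range candidate cluster numbers, default 2:10.
#' @param seed RNG seed for spectral k-means.
#' @return list with `labels`, `k`, `asw`, and the per-k ASW vector.
#' @export
select_k_by_asw <- function(D, algorithm = c("pam", "spectral"),
                            k_range = 2:10, seed = 1) {
  algorithm <- match.arg(algorithm)
  n <- nrow(D)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("no feasible k in range")
  asws <- rep(NA_real_, length(k_range))
  parts <- vector("list", length(k_range))
  S <- 1 - D
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    lab <- tryCatch(
      if (algorithm == "pam") pam_clustering(D, k) else spectral_clustering(S, k, seed),
      error = function(e) NULL)
    if (is.null(lab) || length(unique(lab)) < 2L) next
    parts[[i]] <- lab
    asws[i] <- average_silhouette_width(lab, D)
  }
  if (all(is.na(asws))) stop("no valid clustering for any k")
  best <- which.max(asws)  # first max = smallest k on ties
  list(labels = parts[[best]], k = k_range[best], asw = asws[best],
       asw_by_k = stats::setNames(asws, k_range))
}
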