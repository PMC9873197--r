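#' Sparsify associations by t-test with local-FDR adjustment
#'
#' Each off-diagonal association r is tested against zero with the
#' correlation t-statistic t = r * sqrt((n - 2) / (1 - r^2)).  Two-sided
#' p-values are converted to signed z-scores and the local false discovery
#' rate is estimated with a theoretical N(0,1) null and a Poisson-spline fit
#' of the marginal z density; edges with lfdr >= `lfdr_threshold` are set
#' to zero.  Associations with |r| = 1 are kept unconditionally.
#'
#' @param R association matrix.
#' @param n number of samples used to estimate R.
#' @param lfdr_threshold removal threshold on the local FDR, default 0.2.
#' @return sparsified association matrix (entries either 0 or the original
#'   value).
#' @export
sparsify_ttest <- function(R, n, lfdr_threshold = 0.2) {
  if (n <= 3) stop("t-test sparsification needs n > 3")
  p <- nrow(R)
  ut <- upper.tri(R)
  r <- R[ut]
  sure <- abs(r) >= 1 - 1e-12
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  z <- sign_z_from_t(tstat, df = n - 2)
  lf <- local_fdr(z)
  keep <- (lf < lfdr_threshold) | sure
  out <- R
  vals <- R[ut]
  vals[!keep] <- 0
  out[ut] <- vals
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- 1
  out
}

# signed probit transform of the t statistic (equal-tail z-score)
sign_z_from_t <- function(tstat, df) {
  z <- stats::qnorm(stats::pt(tstat, df = df))
  z[z > 8] <- 8; z[z < -8] <- -8
  z
}

#' Local false discovery rate with a theoretical N(0,1) null
#'
#' Efron-style estimate: the marginal z density is fit by Poisson regression
#' of histogram counts on a natural-spline basis; lfdr(z) =
#' pi0 * dnorm(z) / f(z), clipped at 1, with pi0 estimated from the central
#' mass of the z distribution.
#'
#' @param z vector of z-scores.
#' @param bins number of histogram bins, default 60.
#' @param df spline degrees of freedom, default 7.
#' @return vector of local FDR values in [0, 1].
#' @export
local_fdr <- function(z, bins = 60, df = 7) {
  n <- length(z)
  if (n < 20) {
    # too few tests for a density fit; fall back to BH-style two-sided p
    p <- 2 * stats::pnorm(-abs(z))
    return(pmin(1, stats::p.adjust(p, "BH")))
  }
  br <- seq(min(z) - 1e-8, max(z) + 1e-8, length.out = bins + 1)
  h <- graphics::hist(z, breaks = br, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  binw <- diff(br)[1]
  basis <- splines::ns(mids, df = df)
  fit <- suppressWarnings(stats::glm(counts ~ basis, family = stats::poisson()))
  fz_bin <- pmax(stats::fitted(fit) / (n * binw), 1e-12)
  fhat <- stats::approx(mids, fz_bin, xout = z, rule = 2)$y
  pi0 <- min(1, mean(abs(z) <= 1) / (stats::pnorm(1) - stats::pnorm(-1)))
  pmin(1, pi0 * stats::dnorm(z) / fhat)
}

#' Sparsify associations by a fixed threshold
#'
#' In `"magnitude"` mode (default) edges with |r| < c are removed, so
#' negative associations can survive; `"literal"` mode removes edges with
#' r < c (which also erases all negative associations).
#'
#' @param R association matrix.
#' @param c threshold, default 0.15.
#' @param mode "magnitude" or "literal".
#' @return sparsified association matrix.
#' @export
sparsify_threshold <- function(R, c = 0.15, mode = c("magnitude", "literal")) {
  mode <- match.arg(mode)
  stopifnot(c >= 0, c <= 1)
  out <- R
  drop <- if (mode == "magnitude") abs(R) < c else R < c
  out[drop] <- 0
  diag(out) <- 1
  out
}

#' Sparse partial-association network by neighborhood selection
#'
#' Node-wise lasso regressions on the latent correlation structure
#' (correlation-matrix input, cyclic coordinate descent), with edge support
#' by the OR rule and the penalty chosen by a stability criterion over
#' subsamples: the largest penalty set (densest graph) whose monotonized
#' average edge instability stays below `instability`.  Surviving edges
#' carry the symmetrized regression weight.
#'
#' @param mat mclr-normalized matrix, taxa x samples.
#' @param n_lambda penalty grid size, default 20 (log-spaced).
#' @param lambda_min_ratio smallest penalty as fraction of the largest,
#'   default 0.01.
#' @param n_subsamples stability subsamples, default 20, each of size
#'   floor(0.8 n).
#' @param instability target average edge instability, default 0.05.
#' @param seed RNG seed for the subsampling.
#' @return sparsified association matrix (symmetric, zero diagonal entries
#'   except the unit diagonal; removed edges are 0).
#' @export
neighborhood_selection <- function(mat, n_lambda = 20, lambda_min_ratio = 0.01,
                                   n_subsamples = 20, instability = 0.05,
                                   seed = 1) {
  n <- ncol(mat)
  if (n < 10) stop("neighborhood selection needs at least 10 samples")
  p <- nrow(mat)
  sigma_full <- latent_correlation(mat)
  lmax <- max(abs(sigma_full[upper.tri(sigma_full)]), 0.1)
  lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
  b <- floor(0.8 * n)
  freq <- array(0, dim = c(p, p, n_lambda))
  old <- .Random.seed_save()
  set.seed(seed)
  idx_list <- replicate(n_subsamples, sample.int(n, b), simplify = FALSE)
  .Random.seed_restore(old)
  for (s in idx_list) {
    sig <- latent_correlation(mat[, s, drop = FALSE])
    supp <- mb_support_path(sig, lambdas)
    freq <- freq + supp
  }
  theta <- freq / n_subsamples
  inst <- apply(theta, 3L, function(m) {
    v <- m[upper.tri(m)]
    mean(2 * v * (1 - v))
  })
  # lambdas run dense (small index = large penalty = sparse) to dense;
  # monotonize instability from the sparse end and take the densest
  # penalty still within the target
  inst_mono <- cummax(inst)
  ok <- which(inst_mono <= instability)
  sel <- if (length(ok)) max(ok) else 1L
  beta <- mb_beta(sigma_full, lambdas[sel])
  supp <- (abs(beta) > 0) | (abs(t(beta)) > 0)   # OR rule
  w <- (beta + t(beta)) / 2
  w[!supp] <- 0
  w[w > 1] <- 1; w[w < -1] <- -1
  diag(w) <- 1
  dimnames(w) <- dimnames(sigma_full)
  w
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# support array (p x p x nlambda) of nodewise lasso along the penalty path
mb_support_path <- function(sigma, lambdas) {
  p <- nrow(sigma)
  nl <- length(lambdas)
  supp <- array(FALSE, dim = c(p, p, nl))
  for (j in seq_len(p)) {
    co <- lasso_cov_path_cpp(sigma[-j, -j, drop = FALSE], sigma[-j, j], lambdas)
    nz <- abs(co) > 0
    others <- seq_len(p)[-j]
    for (li in seq_len(nl)) supp[j, others[nz[, li]], li] <- TRUE
  }
  supp | aperm(supp, c(2, 1, 3))   # OR rule per subsample
}

# nodewise lasso coefficients at a single penalty; beta[j, m] is the
# coefficient of node m in node j's regression
mb_beta <- function(sigma, lambda) {
  p <- nrow(sigma)
  beta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    co <- lasso_cov_path_cpp(sigma[-j, -j, drop = FALSE], sigma[-j, j], lambda)
    beta[j, -j] <- co[, 1]
  }
  beta
}

#' Transform associations to dissimilarities
#'
#' `linear`: d = 0.5 (1 - r); `sqrt` (default elsewhere in the pipeline):
#' d = sqrt(0.5 (1 - r)), the metric version.
#'
#' @param R association matrix (entries in [-1, 1]).
#' @param variant "linear" or "sqrt".
#' @return dissimilarity matrix with zero diagonal.
#' @export
association_to_dissimilarity <- function(R, variant = c("sqrt", "linear")) {
  variant <- match.arg(variant)
  if (any(R < -1 - 1e-9) || any(R > 1 + 1e-9)) stop("associations out of [-1, 1]")
  R[R > 1] <- 1; R[R < -1] <- -1
  d <- 0.5 * (1 - R)
  if (variant == "sqrt") d <- sqrt(d)
  diag(d) <- 0
  d
}

#' Build a weighted network from sparsified associations
#'
#' Surviving edges get adjacency a = 1 - d with d from
#' [association_to_dissimilarity()]; removed (zero) associations give a = 0.
#'
#' @param rstar sparsified association matrix.
#' @param variant dissimilarity variant passed on.
#' @return adjacency matrix in [0, 1], zero diagonal.
#' @export
build_network <- function(rstar, variant = c("sqrt", "linear")) {
  variant <- match.arg(variant)
  a <- 1 - association_to_dissimilarity(rstar, variant)
  a[rstar == 0] <- 0
  diag(a) <- 0
  a[a < 0] <- 0; a[a > 1] <- 1
  a
}

#' K-nearest-neighbor sparsification of a scaled dissimilarity matrix
#'
#' Each node is connected to the K nodes with minimum dissimilarity; an
#' edge survives if either endpoint selects the other (union rule).  All
#' other entries are set to 1, the maximum scaled dissimilarity.  Ties at
#' the K-th neighbor are broken by ID (column) order.
#'
#' @param d_scaled dissimilarity matrix scaled to [0, 1].
#' @param K neighbors per node, default 3.
#' @return sparsified dissimilarity matrix.
#' @export
knn_sparsify <- function(d_scaled, K = 3) {
  n <- nrow(d_scaled)
  if (K >= n) stop("K must be smaller than the number of samples")
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(d_scaled[i, ], seq_len(n))  # ID order breaks ties
    nb <- setdiff(ord, i)[seq_len(K)]
    keep[i, nb] <- TRUE
  }
  keep <- keep | t(keep)
  out <- d_scaled
  out[!keep] <- 1
  diag(out) <- 0
  out
}

#' Threshold sparsification of a scaled dissimilarity matrix
#'
#' Entries strictly above `cutoff` are set to 1 (maximum dissimilarity).
#'
#' @param d_scaled dissimilarity matrix scaled to [0, 1].
#' @param cutoff default 0.85.
#' @return sparsified dissimilarity matrix.
#' @export
diss_threshold_sparsify <- function(d_scaled, cutoff = 0.85) {
  stopifnot(cutoff > 0, cutoff < 1)
  out <- d_scaled
  out[out > cutoff] <- 1
  diag(out) <- 0
  out
}

#' Build a sample network from sparsified dissimilarities
#'
#' a = 1 - d*; entries with d* = 1 (sparsified pairs) become 0.
#'
#' @param dstar sparsified scaled dissimilarity matrix.
#' @return adjacency matrix in [0, 1], zero diagonal.
#' @export
sample_network <- function(dstar) {
  a <- 1 - dstar
  diag(a) <- 0
  a[a < 0] <- 0; a[a > 1] <- 1
  a
}
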