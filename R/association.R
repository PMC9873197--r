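#' Pearson or Spearman correlation between taxa
#'
#' Taxa are the variables (rows), samples the observations (columns).
#' Zero-variance taxa get correlation 0 to all others, with a warning.
#'
#' @param mat normalized matrix, taxa x samples.
#' @param method "pearson" or "spearman" (average ranks for ties).
#' @return symmetric association matrix with unit diagonal.
#' @export
taxa_correlation <- function(mat, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(mat) < 3L) stop("need at least 3 samples")
  sds <- apply(mat, 1L, stats::sd)
  r <- suppressWarnings(stats::cor(t(mat), method = method))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance taxa; their correlations set to 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  r[is.na(r)] <- 0
  check_association(r)
}

check_association <- function(r) {
  r <- (r + t(r)) / 2
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r
}

# ---- Gaussian copula bridge functions -------------------------------------
#
# Zero-inflated (truncated) Gaussian copula: the observed value is a strictly
# positive monotone function of a latent standard normal Z when Z > Delta,
# and exactly 0 otherwise, with Delta = qnorm(zero proportion).  The bridge
# F(rho) = E[Kendall tau-a] is expressed through orthant probabilities of
# linearly transformed Gaussian vectors (D1 = Z1' - Z1 etc. for an
# independent copy), which makes each case a small pmvnorm computation:
#   CC (no zeros):          F(rho) = 2/pi * asin(rho)
#   TC (one margin zeroed): two terms, 3-dimensional orthants
#   TT (both zeroed):       four terms, 4-dimensional orthants
# Each formula was validated against Monte-Carlo Kendall tau of the
# generating copula.

bridge_cc <- function(rho) 2 / pi * asin(rho)

# deterministic orthant probability (Miwa quadrature; GenzBretz is Monte
# Carlo and can return NaN for near-singular covariances)
orthant_prob <- function(lower, upper, sigma) {
  mvtnorm::pmvnorm(lower = lower, upper = upper, sigma = sigma,
                   algorithm = mvtnorm::Miwa(steps = 128))[1]
}

bridge_tc <- function(rho, dx) {
  rho <- max(min(rho, 0.99), -0.99)
  S1 <- matrix(c(1, -1, -rho, -1, 2, 2 * rho, -rho, 2 * rho, 2), 3, 3)
  p1 <- orthant_prob(c(dx, 0, 0), rep(Inf, 3), S1)
  S2 <- matrix(c(1, 0, -rho, 0, 1, rho, -rho, rho, 2), 3, 3)
  p2 <- orthant_prob(c(dx, -Inf, 0), c(Inf, dx, Inf), S2)
  px <- stats::pnorm(dx)
  4 * p1 - (1 - px)^2 + 2 * ((1 - px) * px - 2 * p2)
}

bridge_tt <- function(rho, dx, dy) {
  rho <- max(min(rho, 0.99), -0.99)
  phi2 <- function(a, b, r)
    orthant_prob(c(-Inf, -Inf), c(a, b), matrix(c(1, r, r, 1), 2))
  S1 <- matrix(c(1, -1, rho, -rho,
                 -1, 2, -rho, 2 * rho,
                 rho, -rho, 1, -1,
                 -rho, 2 * rho, -1, 2), 4, 4)
  p1 <- orthant_prob(c(dx, 0, dy, 0), rep(Inf, 4), S1)
  bb <- phi2(-dx, -dy, rho)      # P(both observed, one copy)
  T1 <- 4 * p1 - bb^2
  S2 <- matrix(c(1, -1, rho, 0,
                 -1, 2, -rho, rho,
                 rho, -rho, 1, 0,
                 0, rho, 0, 1), 4, 4)
  p2 <- orthant_prob(c(dx, 0, dy, -Inf), c(Inf, Inf, Inf, dy), S2)
  T2 <- 2 * (bb * phi2(-dx, dy, -rho) - 2 * p2)
  # same covariance structure with the two coordinates exchanged
  p3 <- orthant_prob(c(dy, 0, dx, -Inf), c(Inf, Inf, Inf, dx), S2)
  T3 <- 2 * (bb * phi2(dx, -dy, -rho) - 2 * p3)
  T4 <- 2 * (bb * phi2(dx, dy, rho) - phi2(-dx, dy, -rho) * phi2(dx, -dy, -rho))
  T1 + T2 + T3 + T4
}

# cache of monotone bridge curves keyed by pair type and rounded Delta values
.bridge_cache <- new.env(parent = emptyenv())

bridge_curve <- function(type, dx, dy, n_grid = 21) {
  key <- sprintf("%s|%.3f|%.3f", type, dx, dy)
  cur <- .bridge_cache[[key]]
  if (!is.null(cur)) return(cur)
  # |rho| capped at 0.99: beyond that the orthant covariances degenerate,
  # and estimated latent correlations are clipped there anyway
  rho <- seq(-0.99, 0.99, length.out = n_grid)
  f <- switch(type,
    tc = vapply(rho, bridge_tc, numeric(1), dx = dx),
    tt = vapply(rho, bridge_tt, numeric(1), dx = dx, dy = dy))
  f <- cummax(f)  # guard against tiny numerical non-monotonicity
  cur <- list(rho = rho, f = f)
  .bridge_cache[[key]] <- cur
  cur
}

invert_bridge <- function(tau, type, dx = NA, dy = NA,
                          method = c("interp", "exact")) {
  method <- match.arg(method)
  if (type == "cc") return(sin(pi * tau / 2))
  if (method == "exact") {
    fn <- function(r) switch(type, tc = bridge_tc(r, dx), tt = bridge_tt(r, dx, dy)) - tau
    lo <- fn(-0.999); hi <- fn(0.999)
    if (lo >= 0) return(-0.999)
    if (hi <= 0) return(0.999)
    out <- try(stats::uniroot(fn, c(-0.999, 0.999), tol = 1e-6)$root, silent = TRUE)
    if (inherits(out, "try-error")) {
      warning("bridge inversion failed; falling back to sin(pi*tau/2)")
      return(sin(pi * tau / 2))
    }
    return(out)
  }
  cur <- bridge_curve(type, dx, dy)
  if (tau <= cur$f[1]) return(cur$rho[1])
  if (tau >= cur$f[length(cur$f)]) return(cur$rho[length(cur$rho)])
  stats::approx(cur$f, cur$rho, xout = tau, ties = "ordered")$y
}

# Kendall tau-a for all row pairs of a matrix (ties counted as zero
# contributions).  Computed from R's tau-b plus tie counts.
kendall_tau_a <- function(mat) {
  n <- ncol(mat)
  n0 <- n * (n - 1) / 2
  tie_count <- function(x) {
    t <- table(x)
    sum(t * (t - 1) / 2)
  }
  ties <- apply(mat, 1L, tie_count)
  tb <- suppressWarnings(stats::cor(t(mat), method = "kendall"))
  adj <- sqrt((n0 - ties) %o% (n0 - ties)) / n0
  ta <- tb * adj
  ta[!is.finite(ta)] <- 0
  diag(ta) <- 1
  ta
}

#' Latent correlation under a truncated Gaussian copula
#'
#' Semi-parametric rank-based estimate of the latent correlation matrix of
#' a zero-inflated (truncated) Gaussian copula: pairwise Kendall tau-a is
#' estimated and inverted through the bridge function selected per pair by
#' the presence of zeros (truncated/truncated, truncated/continuous, or
#' continuous/continuous), then the result is projected to the nearest
#' positive semidefinite correlation matrix.  Intended for
#' mclr-transformed data (nonnegative, zeros preserved).
#'
#' @param mat mclr-normalized matrix, taxa x samples; zeros mark structural
#'   absences.
#' @param method `"interp"` (default) inverts a cached monotone bridge curve
#'   per truncation-level pair (zero proportions rounded to `delta_round`);
#'   `"exact"` root-finds each pair's bridge to 1e-6.
#' @param delta_round rounding step for the cached truncation thresholds.
#' @return symmetric positive semidefinite correlation matrix.
#' @export
latent_correlation <- function(mat, method = c("interp", "exact"),
                               delta_round = 0.1) {
  method <- match.arg(method)
  if (any(mat < 0)) stop("latent_correlation expects nonnegative (mclr) input")
  p <- nrow(mat)
  tau <- kendall_tau_a(mat)
  p0 <- rowMeans(mat == 0)
  degenerate <- p0 >= 1 - 1e-12 | apply(mat, 1L, function(x) length(unique(x))) < 2L
  if (any(degenerate))
    warning(sum(degenerate), " taxa without variation; latent correlations set to 0")
  delta <- stats::qnorm(pmin(p0, 1 - 1e-12))  # -Inf when no zeros
  delta <- pmin(pmax(delta, -3), 3)
  dr <- if (method == "interp") round(delta / delta_round) * delta_round else delta
  r <- diag(1, p)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    if (degenerate[i] || degenerate[j]) { r[i, j] <- r[j, i] <- 0; next }
    ti <- p0[i] > 0; tj <- p0[j] > 0
    if (ti && tj) {
      d1 <- min(dr[i], dr[j]); d2 <- max(dr[i], dr[j])
      rij <- invert_bridge(tau[i, j], "tt", d1, d2, method = method)
    } else if (ti || tj) {
      rij <- invert_bridge(tau[i, j], "tc", if (ti) dr[i] else dr[j], method = method)
    } else {
      rij <- invert_bridge(tau[i, j], "cc")
    }
    r[i, j] <- r[j, i] <- rij
  }
  dimnames(r) <- list(rownames(mat), rownames(mat))
  nearest_psd_correlation(r)
}

#' Project a symmetric matrix to the nearest positive semidefinite
#' correlation matrix by eigenvalue clipping
#'
#' @param r symmetric matrix.
#' @param eig_floor smallest retained eigenvalue, default 1e-6.
#' @return positive semidefinite matrix with unit diagonal.
#' @export
nearest_psd_correlation <- function(r, eig_floor = 1e-6) {
  e <- eigen((r + t(r)) / 2, symmetric = TRUE)
  if (min(e$values) >= eig_floor) return(check_association(r))
  v <- pmax(e$values, eig_floor)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  if (any(d <= 0)) stop("projection to positive definite correlation failed")
  out <- out / (d %o% d)
  dimnames(out) <- dimnames(r)
  check_association(out)
}

#' Proportionality between clr-transformed taxa
#'
#' rho_p(i, j) = 2 cov(z_i, z_j) / (var(z_i) + var(z_j)) on clr values z;
#' bounded in [-1, 1], equal to 1 iff the clr profiles are identical up to
#' an additive constant.
#'
#' @param clr_mat clr-transformed matrix, taxa x samples.
#' @return symmetric association matrix with unit diagonal.
#' @export
proportionality <- function(clr_mat) {
  cv <- stats::cov(t(clr_mat))
  v <- diag(cv)
  if (any(v == 0)) warning(sum(v == 0), " zero-variance taxa; proportionality set to 0")
  denom <- outer(v, v, "+")
  r <- 2 * cv / denom
  r[denom == 0] <- 0
  r[v == 0, ] <- 0; r[, v == 0] <- 0
  diag(r) <- 1
  check_association(r)
}

#' Sample-to-sample dissimilarities
#'
#' @param mat normalized matrix, taxa x samples; samples are the points.
#'   Pair each measure with its normalization: `aitchison` with clr (it IS
#'   the Euclidean distance between clr compositions), `euclidean` with VST
#'   or mclr, `ckld` with pseudo-counted fractions, `bray-curtis` with mclr.
#' @param measure dissimilarity measure.
#' @return symmetric sample x sample dissimilarity matrix, zero diagonal.
#' @export
sample_dissimilarity <- function(mat,
                                 measure = c("aitchison", "euclidean", "ckld", "bray-curtis")) {
  measure <- match.arg(measure)
  x <- t(mat)  # samples x taxa
  d <- switch(measure,
    aitchison = ,
    euclidean = as.matrix(stats::dist(x, method = "euclidean")),
    ckld = ckld_matrix(mat),
    "bray-curtis" = {
      if (any(x < 0)) stop("bray-curtis requires nonnegative input")
      as.matrix(vegan::vegdist(x, method = "bray"))
    })
  diag(d) <- 0
  dimnames(d) <- list(colnames(mat), colnames(mat))
  d
}

# Compositional Kullback-Leibler divergence, concretized as the
# Jeffreys-symmetrized KL between fraction vectors:
#   d(x, y) = 0.5 * sum_i (x_i - y_i) (log x_i - log y_i)
ckld_matrix <- function(frac) {
  if (any(frac <= 0))
    stop("cKLD requires strictly positive fractions (pseudo count upstream)")
  lf <- log(frac)
  s <- colSums(frac * lf)
  cross <- t(frac) %*% lf
  d <- 0.5 * (outer(s, s, "+") - cross - t(cross))
  d[d < 0] <- 0
  d
}

#' Scale a dissimilarity matrix to [0, 1]
#'
#' Divides by the maximum entry; an all-zero matrix is returned unchanged
#' with a warning.
#'
#' @param d dissimilarity matrix.
#' @return scaled matrix with maximum 1 (unless all-zero).
#' @export
scale_dissimilarity <- function(d) {
  mx <- max(d)
  if (mx <= 0) {
    warning("all-zero dissimilarity matrix; identity scaling")
    return(d)
  }
  d / mx
}
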