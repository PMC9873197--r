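#' Add a pseudo count
#'
#' @param counts count matrix.
#' @param value positive pseudo count, default 1.
#' @return matrix with every entry incremented by `value`.
#' @export
add_pseudocount <- function(counts, value = 1) {
  if (!is.numeric(value) || length(value) != 1L || value <= 0)
    stop("pseudo count must be a positive number")
  counts + value
}

#' Centered log-ratio transformation
#'
#' Per sample (column) x: clr(x)_i = log(x_i) - mean_j log(x_j). Requires
#' strictly positive entries; add a pseudo count first for zero-containing
#' count data.
#'
#' @param mat positive matrix, taxa x samples; samples are compositions.
#' @return clr-transformed matrix (columns sum to zero).
#' @export
clr_transform <- function(mat) {
  if (any(mat <= 0))
    stop("clr requires strictly positive entries; apply add_pseudocount() first")
  lm <- log(mat)
  sweep(lm, 2L, colMeans(lm), "-")
}

#' Modified centered log-ratio transformation
#'
#' Per sample, the clr is computed over the nonzero entries only; zeros stay
#' exactly zero. All nonzero transformed values are then shifted by a common
#' global constant so that the smallest nonzero transformed value equals
#' `eps` (no shift if it is already >= `eps`). This keeps zero and nonzero
#' entries separated, which downstream rank-based estimators rely on.
#'
#' @param counts count matrix, taxa x samples (zeros allowed).
#' @param eps target minimum of the nonzero transformed values, default 1.
#' @return transformed matrix; zeros preserved exactly.
#' @export
mclr_transform <- function(counts, eps = 1) {
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  skipped <- logical(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    x <- counts[, j]
    nz <- x > 0
    if (sum(nz) <= 1L) {
      warning("sample ", colnames(counts)[j] %||% j,
              " has <= 1 nonzero entry; mclr set to all-zero for this sample")
      skipped[j] <- TRUE
      next
    }
    lx <- log(x[nz])
    out[nz, j] <- lx - mean(lx)
  }
  nzall <- counts > 0
  nzall[, skipped] <- FALSE
  if (any(nzall)) {
    mn <- min(out[nzall])
    if (mn < eps) out[nzall] <- out[nzall] + (eps - mn)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variance-stabilizing transformation for overdispersed counts
#'
#' A negative-binomial variance-stabilizing transformation: (i) size factors
#' by median-of-ratios against the geometric-mean reference sample; (ii)
#' per-taxon dispersions by method of moments on normalized counts; (iii) a
#' parametric mean-dispersion trend alpha(mu) = a1/mu + a0 fit by
#' iteratively reweighted gamma regression; (iv) the closed-form NB VST
#' under that trend applied to the normalized counts,
#' u(q) = log2((1 + a1 + 2 a0 q + 2 sqrt(a0 q (1 + a1 + a0 q))) / (4 a0)).
#' The transform is strictly increasing in the counts. Taxon-wise dispersion
#' outliers are not shrunk towards the trend (no empirical Bayes step);
#' the transform is used here only as a monotone normalization upstream of
#' correlation estimation.
#'
#' @param counts positive count matrix, taxa x samples (apply a pseudo count
#'   upstream if zeros are present).
#' @return transformed matrix, same dimensions.
#' @export
vst_transform <- function(counts) {
  if (any(counts <= 0))
    stop("vst requires strictly positive entries; apply add_pseudocount() first")
  loggeo <- rowMeans(log(counts))
  sf <- apply(counts, 2L, function(col) exp(stats::median(log(col) - loggeo)))
  q <- sweep(counts, 2L, sf, "/")
  mu <- rowMeans(q)
  v <- apply(q, 1L, stats::var)
  xi <- mean(1 / sf)
  disp <- pmax((v - xi * mu) / mu^2, 1e-8)
  fit <- fit_dispersion_trend(mu, disp)
  a0 <- fit["a0"]; a1 <- fit["a1"]
  log2((1 + a1 + 2 * a0 * q + 2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
}

# Parametric trend alpha(mu) = a1/mu + a0, fit by iteratively reweighted
# gamma GLM with identity link, excluding extreme dispersion ratios between
# iterations.  Falls back to a0 clipped at 1e-8 if the asymptotic dispersion
# comes out nonpositive.
fit_dispersion_trend <- function(mu, disp, max_iter = 10) {
  use <- disp > 1e-7
  if (sum(use) < 3L) return(c(a0 = 1e-8, a1 = max(mean(disp * mu), 0.1)))
  m <- mu[use]; d <- disp[use]
  coef <- c(a0 = 0.1, a1 = 1)
  for (it in seq_len(max_iter)) {
    fit <- try(suppressWarnings(stats::glm(d ~ I(1 / m),
                 family = stats::Gamma(link = "identity"),
                 start = unname(coef))), silent = TRUE)
    if (inherits(fit, "try-error")) break
    newcoef <- c(a0 = unname(stats::coef(fit)[1]), a1 = unname(stats::coef(fit)[2]))
    if (!all(is.finite(newcoef))) break
    pred <- newcoef["a0"] + newcoef["a1"] / m
    ratio <- d / pmax(pred, 1e-12)
    keep <- ratio > 1e-4 & ratio < 15
    conv <- max(abs(newcoef - coef) / pmax(abs(coef), 1e-8)) < 1e-6
    coef <- newcoef
    if (conv) break
    m <- m[keep]; d <- d[keep]
    if (length(m) < 3L) break
  }
  if (!is.finite(coef["a0"]) || coef["a0"] <= 0) {
    warning("dispersion trend fit gave nonpositive asymptotic dispersion; clipping a0 at 1e-8")
    coef["a0"] <- 1e-8
  }
  if (!is.finite(coef["a1"]) || coef["a1"] < 0) coef["a1"] <- 0
  coef
}

#' Convert counts to fractions (relative abundances)
#'
#' @param counts count matrix, taxa x samples; per-sample depth must be
#'   positive.
#' @return matrix whose columns sum to one.
#' @export
to_fractions <- function(counts) {
  depths <- colSums(counts)
  if (any(depths <= 0)) stop("zero-depth sample; cannot form fractions")
  sweep(counts, 2L, depths, "/")
}

#' Apply a named normalization (zero handling included)
#'
#' Dispatch used by the method grids: `"clr"` and `"vst"` add a pseudo count
#' of 1 first, `"mclr"` handles zeros natively, `"fractions"` adds a pseudo
#' count first (as used upstream of the compositional KLD).
#'
#' @param counts raw count matrix.
#' @param method one of "clr", "mclr", "vst", "fractions".
#' @param pseudocount pseudo count used where required, default 1.
#' @param mclr_eps shift target for mclr, default 1.
#' @return normalized matrix, taxa x samples.
#' @export
normalize_counts <- function(counts, method = c("clr", "mclr", "vst", "fractions"),
                             pseudocount = 1, mclr_eps = 1) {
  method <- match.arg(method)
  switch(method,
    clr = clr_transform(add_pseudocount(counts, pseudocount)),
    mclr = mclr_transform(counts, eps = mclr_eps),
    vst = vst_transform(add_pseudocount(counts, pseudocount)),
    fractions = to_fractions(add_pseudocount(counts, pseudocount)))
}
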