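test_that("t-test sparsification keeps extreme and drops null associations", {
  n <- 100
  R <- matrix(0.0, 4, 4); diag(R) <- 1
  R[1, 2] <- R[2, 1] <- 0.9999
  R[3, 4] <- R[4, 3] <- 0
  dimnames(R) <- list(paste0("t", 1:4), paste0("t", 1:4))
  out <- sparsify_ttest(R, n = n)
  expect_equal(out[1, 2], 0.9999)  # extreme significance kept
  expect_equal(out[3, 4], 0)       # t = 0 removed
  expect_error(sparsify_ttest(R, n = 3), "n > 3")
})

test_that("t-test + lfdr decisions match an independently recomputed two-step oracle", {
  set.seed(21)
  n <- 150; p <- 30
  # half the taxa form two correlated blocks, half are noise
  z <- matrix(rnorm(p * n), p, n)
  z[2:8, ] <- z[2:8, ] * 0.6 + rep(z[1, ], each = 7) * 0.8
  z[10:15, ] <- z[10:15, ] * 0.6 + rep(z[9, ], each = 6) * 0.8
  rownames(z) <- sprintf("t%02d", 1:p); colnames(z) <- sprintf("s%03d", 1:n)
  R <- taxa_correlation(z, "pearson")
  out <- sparsify_ttest(R, n = n, lfdr_threshold = 0.2)
  # oracle: recompute t statistics, z-scores and the same spline-Poisson
  # local FDR definition step by step
  ut <- upper.tri(R)
  r <- R[ut]
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  zsc <- qnorm(pt(tstat, df = n - 2))
  zsc[zsc > 8] <- 8; zsc[zsc < -8] <- -8
  br <- seq(min(zsc) - 1e-8, max(zsc) + 1e-8, length.out = 61)
  h <- hist(zsc, breaks = br, plot = FALSE)
  fit <- suppressWarnings(glm(h$counts ~ splines::ns(h$mids, df = 7), family = poisson()))
  fz <- approx(h$mids, pmax(fitted(fit) / (length(zsc) * diff(br)[1]), 1e-12),
               xout = zsc, rule = 2)$y
  pi0 <- min(1, mean(abs(zsc) <= 1) / (pnorm(1) - pnorm(-1)))
  lfdr <- pmin(1, pi0 * dnorm(zsc) / fz)
  keep_oracle <- lfdr < 0.2
  expect_equal(out[ut] != 0, keep_oracle, ignore_attr = TRUE)
  # sparsification never alters surviving weights
  expect_true(all(out[ut][keep_oracle] == R[ut][keep_oracle]))
})

test_that("threshold sparsification honors both modes and the strict boundary", {
  R <- matrix(c(1, 0.1, 0.2, 0.1, 1, -0.5, 0.2, -0.5, 1), 3, 3,
              dimnames = list(paste0("t", 1:3), paste0("t", 1:3)))
  mag <- sparsify_threshold(R, c = 0.15, mode = "magnitude")
  expect_equal(c(mag[1, 2], mag[1, 3], mag[2, 3]), c(0, 0.2, -0.5))
  lit <- sparsify_threshold(R, c = 0.15, mode = "literal")
  expect_equal(c(lit[1, 2], lit[1, 3], lit[2, 3]), c(0, 0.2, 0))
  # boundary: r equal to c survives (strict <)
  Rb <- matrix(c(1, 0.15, 0.15, 1), 2, 2)
  expect_equal(sparsify_threshold(Rb, 0.15)[1, 2], 0.15)
  expect_equal(formals(sparsify_threshold)$c, 0.15)
  # density non-increasing in c
  set.seed(22)
  Rr <- taxa_correlation(matrix(rnorm(300), 10, 30,
                                dimnames = list(paste0("t", 1:10), paste0("s", 1:30))))
  dens <- sapply(c(0.05, 0.2, 0.4, 0.8),
                 function(cc) mean(sparsify_threshold(Rr, cc)[upper.tri(Rr)] != 0))
  expect_true(all(diff(dens) <= 0))
})

test_that("association-dissimilarity-adjacency chain is monotone with known values", {
  pairm <- function(r) matrix(c(1, r, r, 1), 2)
  dl <- sapply(c(-1, 0, 1), function(r) association_to_dissimilarity(pairm(r), "linear")[1, 2])
  ds <- sapply(c(-1, 0, 1), function(r) association_to_dissimilarity(pairm(r), "sqrt")[1, 2])
  expect_equal(dl, c(1, 0.5, 0))
  expect_equal(ds, c(1, sqrt(0.5), 0))
  expect_error(association_to_dissimilarity(pairm(1.5)), "out of")
  # single surviving edge r = 0.5 -> a = 0.75 under the linear variant
  R <- diag(2); R[1, 2] <- R[2, 1] <- 0.5
  expect_equal(build_network(R, "linear")[1, 2], 0.75)
  empty <- diag(2)
  expect_true(all(build_network(empty) == 0))
  # chain maps [-1, 1] monotonically into [0, 1] (grid avoids exactly 0,
  # which marks a structurally removed edge)
  rr <- seq(-0.99, 0.99, length.out = 20)
  Rm <- diag(21); Rm[1, 2:21] <- Rm[2:21, 1] <- rr; diag(Rm) <- 1
  a <- build_network(Rm, "sqrt")[1, -1]
  expect_true(all(diff(a) >= 0))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("K-NN sparsification applies the union rule", {
  d <- matrix(c(0, 0.1, 0.5, 0.1, 0, 0.9, 0.5, 0.9, 0), 3, 3,
              dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  out <- knn_sparsify(d, K = 1)
  # 1's nearest is 2; 3's nearest is 1 -> edges {1,2} and {1,3} survive
  expect_equal(out[1, 2], 0.1)
  expect_equal(out[1, 3], 0.5)
  expect_equal(out[2, 3], 1)
  expect_equal(formals(knn_sparsify)$K, 3)
  # every node keeps at least K incident edges
  set.seed(23)
  D <- as.matrix(dist(matrix(rnorm(40), 20)))
  ds <- knn_sparsify(scale_dissimilarity(D), K = 3)
  expect_true(all(rowSums(ds < 1 & upper.tri(ds) | ds < 1 & lower.tri(ds)) >= 3))
  expect_error(knn_sparsify(d, K = 3), "smaller")
})

test_that("dissimilarity thresholding is strict and sample networks invert", {
  d <- matrix(c(0, 0.2, 0.85, 0.2, 0, 0.9, 0.85, 0.9, 0), 3, 3,
              dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  out <- diss_threshold_sparsify(d, 0.85)
  expect_equal(out[1, 3], 0.85)  # boundary untouched
  expect_equal(out[2, 3], 1)
  expect_equal(formals(diss_threshold_sparsify)$cutoff, 0.85)
  a <- sample_network(out)
  expect_equal(a[1, 2], 0.8)
  expect_equal(a[2, 3], 0)
  expect_equal(a, t(a))
  all1 <- matrix(1, 3, 3); diag(all1) <- 0
  expect_true(all(sample_network(all1) == 0))
})

test_that("neighborhood selection stays near-empty on independent data", {
  empties <- 0
  for (s in 1:8) {
    spec <- synthetic_spec(n_taxa = 15, n_samples = 500, zero_inflation = 0.2,
                           dispersion = 0.3, seed = 100 + s)
    nul <- generate_null_counts(spec)
    w <- neighborhood_selection(normalize_counts(nul$counts, "mclr"), seed = 1)
    dens <- mean(w[upper.tri(w)] != 0)
    if (dens <= 0.02) empties <- empties + 1
  }
  expect_gte(empties, 7)
})

test_that("neighborhood selection recovers a chain graph", {
  p <- 15; n <- 1000
  prec <- diag(1, p)
  for (i in 1:(p - 1)) prec[i, i + 1] <- prec[i + 1, i] <- -0.45
  sig <- cov2cor(solve(prec))
  set.seed(24)
  z <- t(chol(sig)) %*% matrix(rnorm(p * n), p, n)
  mu <- exp(rnorm(p, log(50), 0.5))
  counts <- matrix(qnbinom(pnorm(z), mu = mu[row(z)], size = 3), p, n)
  dimnames(counts) <- list(sprintf("g%02d", 1:p), sprintf("s%04d", 1:n))
  w <- neighborhood_selection(normalize_counts(counts, "mclr"), seed = 1)
  expect_equal(w, t(w))
  est <- w != 0; diag(est) <- FALSE
  truth <- abs(row(est) - col(est)) == 1
  tp <- sum(est & truth) / 2; fp <- sum(est & !truth) / 2; fn <- sum(!est & truth) / 2
  f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_gte(f1, 0.8)
})
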