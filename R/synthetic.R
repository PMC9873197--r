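#' Specification of a synthetic microbiome cohort
#'
#' Collects every knob of the synthetic generators.  Defaults describe a
#' modest gut-like cohort: 60 genera in 6 families (association blocks),
#' three planted hub genera (5% of taxa, matching the 95%-quantile hub
#' definition), moderately strong within-family associations, zero-inflated
#' overdispersed counts, and log-normal sequencing depths around 20000.
#'
#' @param n_taxa number of taxa (genera), default 60.
#' @param n_samples number of samples, default 300.
#' @param n_families number of taxon families = association blocks,
#'   default 6.
#' @param genera_per_family nominal block size (taxa are dealt into blocks
#'   of this size; the last block absorbs the remainder), default
#'   `ceiling(n_taxa / n_families)`.
#' @param block_correlation latent within-block correlation in [0, 1),
#'   default 0.6.
#' @param n_hub_taxa planted hub taxa, default 3.
#' @param hub_partner_count latent partners per hub, default 20 (about
#'   twice the within-family degree, so planted hubs are genuinely the
#'   best-connected nodes).
#' @param zero_inflation independent Bernoulli zeroing probability,
#'   default 0.3.
#' @param depth_log_mean,depth_log_sd log-normal sequencing-depth
#'   parameters, defaults log(20000) and 0.5.
#' @param dispersion negative-binomial overdispersion (NB size = 1 /
#'   dispersion), default 0.5.
#' @param abundance_log_mean,abundance_log_sd log-normal spread of taxon
#'   mean abundances, defaults log(20) and 1.
#' @param group_rewire_fraction fraction of latent support edges rewired in
#'   group B (two-group generator), default 0.3.
#' @param n_sample_clusters latent sample clusters (enterotype generator),
#'   default 3.
#' @param cluster_separation nonnegative log-scale separation of the
#'   cluster Dirichlet means, default 1.
#' @param dirichlet_precision total Dirichlet concentration per cluster,
#'   default 50.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_taxa = 60, n_samples = 300, n_families = 6,
                           genera_per_family = ceiling(n_taxa / n_families),
                           block_correlation = 0.6, n_hub_taxa = 3,
                           hub_partner_count = 20, zero_inflation = 0.3,
                           depth_log_mean = log(20000), depth_log_sd = 0.5,
                           dispersion = 0.5,
                           abundance_log_mean = log(20), abundance_log_sd = 1,
                           group_rewire_fraction = 0.3,
                           n_sample_clusters = 3, cluster_separation = 1,
                           dirichlet_precision = 50, seed = 1) {
  spec <- list(n_taxa = n_taxa, n_samples = n_samples, n_families = n_families,
               genera_per_family = genera_per_family,
               block_correlation = block_correlation, n_hub_taxa = n_hub_taxa,
               hub_partner_count = hub_partner_count,
               zero_inflation = zero_inflation,
               depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
               dispersion = dispersion,
               abundance_log_mean = abundance_log_mean,
               abundance_log_sd = abundance_log_sd,
               group_rewire_fraction = group_rewire_fraction,
               n_sample_clusters = n_sample_clusters,
               cluster_separation = cluster_separation,
               dirichlet_precision = dirichlet_precision, seed = seed)
  with(spec, {
    stopifnot(n_taxa >= 2, n_samples >= 2, n_families >= 1,
              genera_per_family >= 1, n_hub_taxa >= 0, hub_partner_count >= 0,
              dispersion > 0, dirichlet_precision > 0, n_sample_clusters >= 1)
    if (block_correlation < 0 || block_correlation >= 1)
      stop("block_correlation must be in [0, 1)")
    if (zero_inflation < 0 || zero_inflation > 1)
      stop("zero_inflation must be a probability")
    if (group_rewire_fraction < 0 || group_rewire_fraction > 1)
      stop("group_rewire_fraction must be a probability")
    if (cluster_separation < 0) stop("cluster_separation must be nonnegative")
  })
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic cohort spec:", x$n_taxa, "taxa x", x$n_samples, "samples,",
      x$n_families, "families,", x$n_hub_taxa, "hubs, seed", x$seed, "\n")
  invisible(x)
}

taxon_ids <- function(p) sprintf("g%03d", seq_len(p))
sample_ids <- function(n, prefix = "s") sprintf("%s%04d", prefix, seq_len(n))

family_blocks <- function(spec) {
  p <- spec$n_taxa
  fam <- pmin(((seq_len(p) - 1L) %/% spec$genera_per_family) + 1L, spec$n_families)
  fam
}

make_taxonomy <- function(spec) {
  p <- spec$n_taxa
  fam <- family_blocks(spec)
  data.frame(taxon_id = taxon_ids(p), genus = taxon_ids(p),
             family = sprintf("f%02d", fam), stringsAsFactors = FALSE)
}

# latent structure: family blocks, hub indices, hub partner sets
latent_structure <- function(spec) {
  p <- spec$n_taxa
  fam <- family_blocks(spec)
  hubs <- integer(0)
  partner_sets <- list()
  if (spec$n_hub_taxa > 0) {
    # one hub per family, spread over blocks
    hubs <- vapply(seq_len(spec$n_hub_taxa), function(h) {
      block <- ((h - 1L) %% spec$n_families) + 1L
      members <- which(fam == block)
      members[((h - 1L) %/% spec$n_families) %% length(members) + 1L]
    }, integer(1))
    for (h in hubs) {
      pool <- setdiff(which(fam != fam[h]), hubs)
      partner_sets[[as.character(h)]] <-
        sample(pool, min(spec$hub_partner_count, length(pool)))
    }
  }
  list(fam = fam, hubs = hubs, partner_sets = partner_sets)
}

# Latent correlation as an explicit factor model: one factor per family
# (loading sqrt(block_correlation) for its non-hub members) and one factor
# per hub (loading ~0.95 on the hub itself, and on each partner the largest
# loading its family membership leaves room for).  Positive definite by
# construction, so hub rows are not crushed by a PSD projection; hubs load
# only on their own factor, which makes them bridges between blocks.
factor_correlation <- function(spec, st) {
  p <- spec$n_taxa
  bc <- spec$block_correlation
  n_fac <- spec$n_families + length(st$hubs)
  L <- matrix(0, p, n_fac)
  is_hub <- seq_len(p) %in% st$hubs
  for (i in seq_len(p)) if (!is_hub[i]) L[i, st$fam[i]] <- sqrt(bc)
  a <- 0.95
  for (hi in seq_along(st$hubs)) {
    h <- st$hubs[hi]
    fac <- spec$n_families + hi
    L[h, fac] <- a
    b <- min(if (bc > 0) bc / a else 0.5, sqrt(max(0.98 - bc, 0)))
    for (pr in st$partner_sets[[as.character(h)]]) L[pr, fac] <- b
  }
  resid <- pmax(1 - rowSums(L^2), 1e-6)
  sigma <- L %*% t(L) + diag(resid)
  d <- sqrt(diag(sigma))
  sigma <- sigma / (d %o% d)
  nearest_psd_correlation(sigma)
}

# edge support implied by the latent structure (block pairs among non-hub
# members plus hub-partner pairs); used by the two-group generator
structure_support <- function(spec, st) {
  p <- spec$n_taxa
  is_hub <- seq_len(p) %in% st$hubs
  supp <- outer(st$fam, st$fam, "==") & !outer(is_hub, is_hub, "|")
  diag(supp) <- FALSE
  for (h in st$hubs) {
    for (pr in st$partner_sets[[as.character(h)]]) {
      supp[h, pr] <- supp[pr, h] <- TRUE
    }
  }
  supp
}

support_to_correlation <- function(supp, rho) {
  sigma <- ifelse(supp, rho, 0)
  diag(sigma) <- 1
  nearest_psd_correlation(sigma)
}

# counts from a latent Gaussian copula with NB marginals, Bernoulli zero
# inflation and multinomial depth resampling
counts_from_latent <- function(sigma, spec, n = spec$n_samples, prefix = "s") {
  p <- spec$n_taxa
  mu <- exp(stats::rnorm(p, spec$abundance_log_mean, spec$abundance_log_sd))
  ch <- chol(sigma + diag(1e-8, p))
  z <- t(ch) %*% matrix(stats::rnorm(p * n), p, n)
  u <- stats::pnorm(z)
  size <- 1 / spec$dispersion
  counts <- matrix(stats::qnbinom(u, mu = mu[row(u)], size = size), p, n)
  if (spec$zero_inflation > 0) {
    mask <- matrix(stats::runif(p * n) < spec$zero_inflation, p, n)
    counts[mask] <- 0
  }
  depths <- round(stats::rlnorm(n, spec$depth_log_mean, spec$depth_log_sd))
  for (j in seq_len(n)) {
    tot <- sum(counts[, j])
    if (tot > 0 && depths[j] > 0)
      counts[, j] <- stats::rmultinom(1, size = depths[j], prob = counts[, j])
    else counts[, j] <- 0
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(taxon_ids(p), sample_ids(n, prefix))
  counts
}

#' Generate counts with planted taxon-association blocks and hub taxa
#'
#' Builds a block-structured latent correlation matrix (families as
#' blocks, hub rows with strong off-block partners), projects it to the
#' nearest positive-definite correlation, samples latent Gaussian vectors,
#' maps them through taxon-specific negative-binomial quantiles, applies
#' Bernoulli zero inflation, and resamples each sample multinomially to a
#' log-normal target depth.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `counts`, `taxonomy`, and `truth` (taxon block labels
#'   and planted hub IDs).
#' @export
generate_taxon_structured_counts <- function(spec) {
  old <- .Random.seed_save()
  set.seed(spec$seed)
  st <- latent_structure(spec)
  sigma <- factor_correlation(spec, st)
  counts <- counts_from_latent(sigma, spec)
  .Random.seed_restore(old)
  truth <- list(taxon_block_labels = stats::setNames(family_blocks(spec),
                                                     taxon_ids(spec$n_taxa)),
                hub_taxa = taxon_ids(spec$n_taxa)[st$hubs],
                latent_correlation = sigma)
  list(counts = counts, taxonomy = make_taxonomy(spec), truth = truth)
}

#' Generate two-group counts with structurally different latent networks
#'
#' Group A uses the planted block + hub support; group B's latent support
#' equals A's with `group_rewire_fraction` of its edges rewired uniformly
#' at random (removed and replaced by previously absent pairs).  Marginals
#' (taxon means, dispersion, depths, zero inflation) are identical.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `counts_a`, `counts_b`, `taxonomy`, `truth` (the two
#'   latent supports).
#' @export
generate_two_group_counts <- function(spec) {
  if (spec$group_rewire_fraction > 1) stop("rewire fraction > 1")
  old <- .Random.seed_save()
  set.seed(spec$seed)
  st <- latent_structure(spec)
  suppA <- structure_support(spec, st)
  ut <- which(upper.tri(suppA), arr.ind = TRUE)
  edges <- which(suppA[upper.tri(suppA)])
  non_edges <- which(!suppA[upper.tri(suppA)])
  n_rewire <- round(spec$group_rewire_fraction * length(edges))
  suppB <- suppA
  if (n_rewire > 0 && length(edges) && length(non_edges)) {
    n_rewire <- min(n_rewire, length(edges), length(non_edges))
    drop <- sample(edges, n_rewire)
    add <- sample(non_edges, n_rewire)
    for (e in drop) { i <- ut[e, 1]; j <- ut[e, 2]; suppB[i, j] <- suppB[j, i] <- FALSE }
    for (e in add) { i <- ut[e, 1]; j <- ut[e, 2]; suppB[i, j] <- suppB[j, i] <- TRUE }
  }
  sigmaA <- support_to_correlation(suppA, spec$block_correlation)
  sigmaB <- support_to_correlation(suppB, spec$block_correlation)
  # same marginal machinery for both groups; separate draws
  mu_seed <- sample.int(.Machine$integer.max %/% 2, 2)
  set.seed(mu_seed[1])
  counts_a <- counts_from_latent(sigmaA, spec, prefix = "a")
  set.seed(mu_seed[2])
  counts_b <- counts_from_latent(sigmaB, spec, prefix = "b")
  .Random.seed_restore(old)
  list(counts_a = counts_a, counts_b = counts_b, taxonomy = make_taxonomy(spec),
       truth = list(support_a = suppA, support_b = suppB,
                    hub_taxa = taxon_ids(spec$n_taxa)[st$hubs]))
}

#' Generate samples from a Dirichlet-multinomial mixture of enterotypes
#'
#' Each sample is drawn from one of `n_sample_clusters` Dirichlet-
#' multinomial components.  The component Dirichlet means share a common
#' log-normal base profile tilted by cluster-specific Gaussian log-fold
#' changes of size `cluster_separation`; `cluster_separation = 0` makes
#' all components identical.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `counts`, `taxonomy`, `truth` (sample cluster labels).
#' @export
generate_enterotype_counts <- function(spec) {
  if (spec$cluster_separation < 0) stop("cluster_separation must be nonnegative")
  k <- spec$n_sample_clusters
  p <- spec$n_taxa; n <- spec$n_samples
  old <- .Random.seed_save()
  set.seed(spec$seed)
  base <- exp(stats::rnorm(p, spec$abundance_log_mean, spec$abundance_log_sd))
  tilts <- matrix(stats::rnorm(p * k), p, k) * spec$cluster_separation
  means <- sweep(exp(tilts), 1L, base, "*")
  means <- sweep(means, 2L, colSums(means), "/")
  labels <- sample.int(k, n, replace = TRUE)
  depths <- round(stats::rlnorm(n, spec$depth_log_mean, spec$depth_log_sd))
  counts <- matrix(0, p, n)
  for (j in seq_len(n)) {
    alpha <- means[, labels[j]] * spec$dirichlet_precision
    g <- stats::rgamma(p, shape = alpha, rate = 1)
    if (sum(g) == 0) g <- alpha
    pr <- g / sum(g)
    if (depths[j] > 0) counts[, j] <- stats::rmultinom(1, depths[j], pr)
  }
  .Random.seed_restore(old)
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(taxon_ids(p), sample_ids(n, "e"))
  list(counts = counts, taxonomy = make_taxonomy(spec),
       truth = list(sample_cluster_labels = stats::setNames(labels, colnames(counts))))
}

#' Generate null counts with no planted structure
#'
#' Identity latent correlation: no association blocks, hubs, group
#' differences or sample clusters; marginals and depth machinery are the
#' same as in the structured generators.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `counts` and `taxonomy`.
#' @export
generate_null_counts <- function(spec) {
  old <- .Random.seed_save()
  set.seed(spec$seed)
  counts <- counts_from_latent(diag(spec$n_taxa), spec)
  .Random.seed_restore(old)
  list(counts = counts, taxonomy = make_taxonomy(spec))
}

#' Write a synthetic dataset to TSV files
#'
#' @param data list from a generator (`counts`, `taxonomy`, optional
#'   `truth`).
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
write_synthetic_dataset <- function(data, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, paste0(prefix, "_counts.tsv")),
             taxonomy = file.path(dir, paste0(prefix, "_taxonomy.tsv")))
  write_count_table(data$counts, paths["counts"])
  utils::write.table(data$taxonomy, paths["taxonomy"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(data$truth$sample_cluster_labels)) {
    paths["truth"] <- file.path(dir, paste0(prefix, "_truth.tsv"))
    utils::write.table(
      data.frame(sample_id = names(data$truth$sample_cluster_labels),
                 cluster = data$truth$sample_cluster_labels),
      paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Serialize / restore a synthetic spec as JSON
#'
#' @param spec a [synthetic_spec()].
#' @param path JSON file path.
#' @return `write_synthetic_spec` returns the path invisibly;
#'   `read_synthetic_spec` returns the validated spec.
#' @export
write_synthetic_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synthetic_spec, vals)
}
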