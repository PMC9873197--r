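test_that("structured generator produces valid, reproducible count matrices", {
  spec <- synthetic_spec(n_taxa = 40, n_samples = 200, seed = 1)
  d <- generate_taxon_structured_counts(spec)
  expect_equal(dim(d$counts), c(40, 200))
  expect_true(all(d$counts >= 0))
  expect_true(all(d$counts == round(d$counts)))
  expect_equal(rownames(d$counts), d$taxonomy$taxon_id)
  expect_setequal(names(d$truth$taxon_block_labels), rownames(d$counts))
  expect_length(d$truth$hub_taxa, spec$n_hub_taxa)
  # bit-identical under the same spec + seed, different under another seed
  d2 <- generate_taxon_structured_counts(spec)
  expect_identical(d$counts, d2$counts)
  d3 <- generate_taxon_structured_counts(synthetic_spec(n_taxa = 40, n_samples = 200, seed = 2))
  expect_false(identical(d$counts, d3$counts))
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(synthetic_spec(block_correlation = 1), "block_correlation")
  expect_error(synthetic_spec(zero_inflation = 1.2), "probability")
  expect_error(synthetic_spec(group_rewire_fraction = 2), "probability")
  expect_error(synthetic_spec(cluster_separation = -1), "nonnegative")
})

test_that("depths follow the specified log-normal and equal-depth limit", {
  spec <- synthetic_spec(n_taxa = 30, n_samples = 1000, seed = 3)
  d <- generate_null_counts(spec)
  depths <- colSums(d$counts)
  ks <- suppressWarnings(
    ks.test(depths, "plnorm", spec$depth_log_mean, spec$depth_log_sd))
  expect_lt(unname(ks$statistic), 0.1)
  # zero inflation off + zero depth spread: equal depths, almost no zeros
  # among well-observed taxa (Monte-Carlo over seeds)
  zf <- sapply(1:20, function(s) {
    sp <- synthetic_spec(n_taxa = 20, n_samples = 60, zero_inflation = 0,
                         depth_log_sd = 0, depth_log_mean = log(20 * 100),
                         abundance_log_mean = log(100), abundance_log_sd = 0.3,
                         seed = s)
    dd <- generate_null_counts(sp)$counts
    expect_equal(length(unique(colSums(dd))), 1)
    mu <- rowMeans(dd)
    mean(dd[mu >= 50, ] == 0)
  })
  expect_lt(mean(zf), 0.05)
})

test_that("within-block associations exceed between-block associations", {
  spec <- synthetic_spec(n_taxa = 40, n_samples = 1000, block_correlation = 0.7,
                         seed = 2)
  d <- generate_taxon_structured_counts(spec)
  R <- taxa_correlation(normalize_counts(d$counts, "mclr"), "spearman")
  blk <- d$truth$taxon_block_labels
  same <- outer(blk, blk, "==") & upper.tri(R)
  diff <- !outer(blk, blk, "==") & upper.tri(R)
  expect_gt(mean(R[same]), mean(R[diff]))
  # oracle: the latent correlation that generated the data shows the same gap
  sig <- d$truth$latent_correlation
  expect_gt(mean(sig[same]), mean(sig[diff]))
})

test_that("two-group generator rewires exactly as requested", {
  spec0 <- synthetic_spec(n_taxa = 30, n_samples = 80, group_rewire_fraction = 0,
                          seed = 5)
  g0 <- generate_two_group_counts(spec0)
  expect_identical(g0$truth$support_a, g0$truth$support_b)
  spec5 <- synthetic_spec(n_taxa = 30, n_samples = 80, group_rewire_fraction = 0.5,
                          seed = 5)
  g5 <- generate_two_group_counts(spec5)
  jac <- function(a, b) {
    ea <- a[upper.tri(a)]; eb <- b[upper.tri(b)]
    sum(ea & eb) / sum(ea | eb)
  }
  expect_lt(jac(g5$truth$support_a, g5$truth$support_b), 1)
  # support overlap decreases monotonically in the rewire fraction
  jacs <- sapply(1:20, function(s) {
    j1 <- jac2 <- NA
    for (fr in c(0.1, 0.5)) {
      sp <- synthetic_spec(n_taxa = 30, n_samples = 50,
                           group_rewire_fraction = fr, seed = 700 + s)
      g <- generate_two_group_counts(sp)
      if (fr == 0.1) j1 <- jac(g$truth$support_a, g$truth$support_b)
      else jac2 <- jac(g$truth$support_a, g$truth$support_b)
    }
    c(j1, jac2)
  })
  expect_gt(mean(jacs[1, ]), mean(jacs[2, ]))
  expect_error(generate_two_group_counts(synthetic_spec(group_rewire_fraction = 1.5)),
               "probability")
})

test_that("enterotype generator plants recoverable or null sample clusters", {
  one <- generate_enterotype_counts(synthetic_spec(n_sample_clusters = 1, seed = 6,
                                                   n_taxa = 20, n_samples = 40))
  expect_equal(length(unique(one$truth$sample_cluster_labels)), 1)
  # strong separation: PAM on the Aitchison distance recovers the labels
  aris <- sapply(1:5, function(s) {
    e <- generate_enterotype_counts(synthetic_spec(
      n_taxa = 30, n_samples = 150, n_sample_clusters = 3,
      cluster_separation = 2, seed = s))
    D <- scale_dissimilarity(sample_dissimilarity(
      normalize_counts(e$counts, "clr"), "aitchison"))
    adjusted_rand_index(pam_clustering(D, 3), e$truth$sample_cluster_labels)
  })
  expect_true(all(aris >= 0.9))
  # zero separation: recovery collapses to chance
  aris0 <- sapply(1:20, function(s) {
    e <- generate_enterotype_counts(synthetic_spec(
      n_taxa = 20, n_samples = 60, n_sample_clusters = 3,
      cluster_separation = 0, seed = 800 + s))
    D <- scale_dissimilarity(sample_dissimilarity(
      normalize_counts(e$counts, "clr"), "aitchison"))
    adjusted_rand_index(pam_clustering(D, 3), e$truth$sample_cluster_labels)
  })
  expect_lt(abs(mean(aris0)), 0.05)
})

test_that("null generator has no planted association structure", {
  spec <- synthetic_spec(n_taxa = 30, n_samples = 1000, seed = 7)
  d <- generate_null_counts(spec)
  R <- taxa_correlation(normalize_counts(d$counts, "mclr"), "spearman")
  expect_lt(mean(abs(R[upper.tri(R)])), 0.1)
  expect_identical(d$counts, generate_null_counts(spec)$counts)
  # heavy zero inflation shows up in the observed zero fraction
  d9 <- generate_null_counts(synthetic_spec(n_taxa = 30, n_samples = 400,
                                            zero_inflation = 0.9, seed = 8))
  expect_lt(abs(mean(d9$counts == 0) - 0.9), 0.05)
})

test_that("synthetic datasets round-trip to TSV files", {
  e <- generate_enterotype_counts(synthetic_spec(n_taxa = 10, n_samples = 15, seed = 9))
  dir <- tempfile()
  paths <- write_synthetic_dataset(e, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(read_count_table(paths["counts"]), e$counts)
  tax <- read_taxonomy(paths["taxonomy"])
  expect_equal(tax$taxon_id, e$taxonomy$taxon_id)
})
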