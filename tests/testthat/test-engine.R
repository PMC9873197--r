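test_that("split plans are disjoint, sized, stratified and reproducible", {
  ids <- sprintf("s%03d", 1:60)
  plans <- draw_splits(ids, n = 20, repetitions = 5, seed = 3)
  expect_length(plans, 5)
  for (p in plans) {
    expect_length(p$discovery, 20)
    expect_length(p$validation, 20)
    expect_length(intersect(p$discovery, p$validation), 0)
  }
  expect_identical(draw_splits(ids, 20, 5, seed = 3), plans)
  expect_equal(formals(draw_splits)$repetitions, 50)
  strata <- rep(c("A", "B"), each = 30)
  sp <- draw_splits(ids, n = 10, repetitions = 3, strata = strata, seed = 1)
  for (p in sp) {
    expect_equal(as.vector(table(strata[match(p$discovery, ids)])), c(5, 5))
    expect_equal(as.vector(table(strata[match(p$validation, ids)])), c(5, 5))
  }
  expect_error(draw_splits(ids, n = 40, repetitions = 2, strata = strata, seed = 1),
               "stratum A")
  expect_error(draw_splits(ids, n = 31, repetitions = 2, seed = 1), "2n")
})

test_that("combination grids reproduce the published counts and sub-counts", {
  g1 <- enumerate_combos(1)
  expect_equal(nrow(g1), 58)
  expect_equal(sum(g1$route == "dissimilarity"), 16)
  expect_equal(sum(g1$route == "network"), 42)
  expect_equal(nrow(enumerate_combos(2)), 14)
  expect_equal(nrow(enumerate_combos(3)), 14)
  g4 <- enumerate_combos(4)
  expect_equal(nrow(g4), 31)
  expect_equal(sum(g4$route == "network"), 20)
  expect_equal(sum(g4$route == "dissimilarity"), 10)
  expect_equal(sum(g4$algorithm == "dmm"), 1)
  for (t in 1:4) {
    g <- enumerate_combos(t)
    expect_false(anyDuplicated(g$id) > 0)
    expect_identical(g, enumerate_combos(t))   # deterministic order
  }
  # reduced presets: 5 / 3 / 3 / 5 combinations, all from the full grids
  sizes <- c(5, 3, 3, 5)
  for (t in 1:4) {
    r <- reduced_combo_preset(t)
    expect_equal(nrow(r), sizes[t])
    expect_true(all(r$id %in% enumerate_combos(t)$id))
  }
})

test_that("selection picks the best discovery combo and re-runs it on validation", {
  spec <- synthetic_spec(n_taxa = 24, n_samples = 160, n_families = 4,
                         zero_inflation = 0.1, dispersion = 0.2, seed = 10)
  d <- generate_taxon_structured_counts(spec)
  data <- list(counts = d$counts, taxonomy = d$taxonomy)
  g1 <- enumerate_combos(1)
  combos <- g1[g1$id %in% c("pseudo|clr|pearson|hierarchical",
                            "none|mclr|spearman|spectral"), ]
  split <- draw_splits(colnames(d$counts), 40, 1, seed = 4)[[1]]
  row <- run_task_on_split(1, split, data, combos, default_params())
  # recompute both combos directly: recorded value must be their maximum
  vals <- sapply(seq_len(nrow(combos)), function(i)
    eval_combo_task1(d$counts[, split$discovery], d$taxonomy, combos[i, ],
                     default_params())$value)
  expect_equal(row$value_discov, max(vals))
  expect_equal(row$combo, combos$id[which.max(vals)])
  # single-combo run selects that combo
  row1 <- run_task_on_split(1, split, data, combos[1, ], default_params())
  expect_equal(row1$combo, combos$id[1])
  expect_false(is.na(row1$value_valid))
  expect_false(is.na(row1$ari_stab))
})

test_that("a constructed dominant combination wins every repetition", {
  # four clean blocks, no zero inflation, mild dispersion; hierarchical
  # clustering at k = n_families reaches ARI 1 on every split and cannot
  # be beaten, so it must be selected in all repetitions
  spec <- synthetic_spec(n_taxa = 24, n_samples = 200, n_families = 4,
                         n_hub_taxa = 0, zero_inflation = 0, dispersion = 0.1,
                         block_correlation = 0.8, seed = 11)
  d <- generate_taxon_structured_counts(spec)
  g1 <- enumerate_combos(1)
  combos <- g1[g1$id %in% c("pseudo|clr|pearson|hierarchical",
                            "pseudo|clr|pearson|ttest|fastgreedy"), ]
  params <- default_params()
  params$k_taxa <- 4
  res <- run_overoptimism_experiment(list(counts = d$counts, taxonomy = d$taxonomy),
                                     1, n = 60, repetitions = 3,
                                     combos = combos, seed = 5, params = params)
  expect_equal(unique(res$combo), "pseudo|clr|pearson|hierarchical")
  expect_equal(res$value_discov, rep(1, 3))
})

test_that("task-2 and task-3 engines produce their criteria end to end", {
  spec <- synthetic_spec(n_taxa = 30, n_samples = 240, n_families = 6,
                         zero_inflation = 0.1, dispersion = 0.3, seed = 12)
  d <- generate_taxon_structured_counts(spec)
  data <- list(counts = d$counts, taxonomy = d$taxonomy)
  g2 <- enumerate_combos(2)
  sub2 <- g2[g2$assoc %in% c("pearson", "spearman") & g2$sparsifier == "threshold", ]
  r2 <- run_overoptimism_experiment(data, 2, n = 60, repetitions = 2,
                                    combos = sub2, seed = 6)
  expect_true(all(r2$value_discov == floor(r2$value_discov)))  # hub counts
  expect_true(all(r2$jaccard >= 0 & r2$jaccard <= 1, na.rm = TRUE))
  # task 3 on a two-group population with strata
  tg <- generate_two_group_counts(synthetic_spec(n_taxa = 24, n_samples = 150,
                                                 group_rewire_fraction = 0.4,
                                                 seed = 13))
  counts <- cbind(tg$counts_a, tg$counts_b)
  strata <- setNames(rep(c("A", "B"), times = c(ncol(tg$counts_a), ncol(tg$counts_b))),
                     colnames(counts))
  d3 <- list(counts = counts, taxonomy = tg$taxonomy, strata = strata)
  r3 <- run_overoptimism_experiment(d3, 3, n = 60, repetitions = 2,
                                    combos = sub2, seed = 7)
  expect_true(all(r3$value_discov >= 0))   # GCD is nonnegative
  expect_false(any(is.na(r3$value_valid)))
})

test_that("over-optimism summaries compute the documented statistics", {
  res <- data.frame(task = 1, n = 100, rep = 1:3,
                    value_discov = c(1, 2, 3) + c(1, 2, 3),
                    value_valid = c(1, 2, 3),
                    k_discov = 2, k_valid = 2, ari_stab = NA, jaccard = NA,
                    cosine = NA, combo = "x", failed = 0)
  # deltas are -1, -2, -3
  s <- summarize_overoptimism(res)
  expect_equal(s$mean_delta, -2)
  expect_equal(s$median_delta, -2)
  expect_equal(s$sd_delta, 1)
  expect_equal(s$effect_size, -2)
  # all-zero deltas: effect size reported as 0
  res0 <- res; res0$value_valid <- res0$value_discov
  expect_equal(summarize_overoptimism(res0)$effect_size, 0)
  # scaled deltas exclude repetitions with a zero discovery value
  resz <- res; resz$value_discov[1] <- 0
  sz <- summarize_overoptimism(resz)
  expect_equal(sz$n_scaled_excluded, 1)
  expect_equal(sz$mean_scaled, mean(c(2 - 4, 3 - 6) / c(4, 6)))
})

test_that("stability summaries cover tasks 1 and 2", {
  res <- data.frame(task = c(1, 1, 2, 2), n = 100, rep = c(1, 2, 1, 2),
                    value_discov = 1, value_valid = 1, k_discov = 2, k_valid = 2,
                    ari_stab = c(1, 0.5, NA, NA),
                    jaccard = c(NA, NA, 0.5, 1),
                    cosine = c(NA, NA, 0.9, 1),
                    combo = "x", failed = 0)
  st <- stability_analysis(res)
  expect_equal(st$ari_stab_mean[st$task == 1], 0.75)
  expect_equal(st$jaccard_mean[st$task == 2], 0.75)
  expect_equal(st$cosine_median[st$task == 2], 0.95)
  expect_error(stability_analysis(res[res$task == 99, ]), "tasks 1 and 2")
})

test_that("experiments are deterministic given the master seed", {
  spec <- synthetic_spec(n_taxa = 20, n_samples = 120, seed = 14)
  nul <- generate_null_counts(spec)
  data <- list(counts = nul$counts, taxonomy = nul$taxonomy)
  g1 <- enumerate_combos(1)
  combos <- g1[g1$id %in% c("pseudo|clr|pearson|hierarchical",
                            "pseudo|clr|spearman|spectral"), ]
  r1 <- run_overoptimism_experiment(data, 1, 30, repetitions = 2, combos = combos, seed = 9)
  r2 <- run_overoptimism_experiment(data, 1, 30, repetitions = 2, combos = combos, seed = 9)
  expect_identical(r1, r2)
})

test_that("reduced runs validate their subset and reproduce the full pipeline", {
  spec <- synthetic_spec(n_taxa = 20, n_samples = 120, seed = 15)
  nul <- generate_null_counts(spec)
  data <- list(counts = nul$counts, taxonomy = nul$taxonomy)
  g1 <- enumerate_combos(1)
  combos <- g1[g1$id %in% c("pseudo|clr|pearson|hierarchical",
                            "pseudo|clr|spearman|spectral"), ]
  red <- reduced_combo_run(data, 1, 30, repetitions = 2, subset = combos, seed = 9)
  full <- summarize_overoptimism(
    run_overoptimism_experiment(data, 1, 30, repetitions = 2, combos = combos, seed = 9))
  expect_equal(red, full, ignore_attr = TRUE)
  expect_error(reduced_combo_run(data, 1, 30, subset = combos[0, ]), "empty")
  bad <- combos; bad$id[1] <- "not|a|combo"
  expect_error(reduced_combo_run(data, 1, 30, subset = bad), "unknown")
})

test_that("summary rendering and manifests round-trip", {
  res <- data.frame(task = 1, n = 100, rep = 1:2, value_discov = c(0.5, 0.6),
                    value_valid = c(0.4, 0.5), k_discov = 2, k_valid = 2,
                    ari_stab = NA, jaccard = NA, cosine = NA, combo = "x", failed = 0)
  s <- summarize_overoptimism(res)
  lines <- capture.output(report_summary(s))
  expect_match(lines[1], "task")
  expect_length(lines, 2)
  tf <- tempfile(fileext = ".json")
  write_manifest(tf, list(task = 1, n = 100), seed = 9)
  man <- jsonlite::read_json(tf)
  expect_equal(man$seed, 9)
  expect_equal(man$config$task, 1)
})
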