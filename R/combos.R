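#' Default pipeline parameters
#'
#' Collects the fixed tuning constants of the method grids: association
#' threshold c = 0.15, local-FDR threshold 0.2, K = 3 nearest neighbors,
#' scaled-dissimilarity cutoff 0.85, k = 10 for taxon clustering, k in
#' 2..10 selected by ASW for sample clustering, square-root
#' association-to-dissimilarity transform.
#'
#' @param seed RNG seed used by seeded algorithms (spectral k-means, DMM
#'   initialization, neighborhood-selection subsampling).
#' @param assoc_threshold threshold c for association sparsification.
#' @param threshold_mode "magnitude" or "literal" (see
#'   [sparsify_threshold()]).
#' @param lfdr_threshold local-FDR removal threshold.
#' @param diss_variant "sqrt" or "linear" association-to-dissimilarity
#'   transform.
#' @param k_taxa fixed number of clusters for hierarchical/spectral taxon
#'   clustering.
#' @param k_range candidate k for ASW-selected sample clustering.
#' @param knn_k K for K-NN sparsification of sample dissimilarities.
#' @param diss_cutoff threshold for dissimilarity sparsification.
#' @param dmm_k_max largest number of DMM components tried.
#' @return named list of parameters.
#' @export
default_params <- function(seed = 1, assoc_threshold = 0.15,
                           threshold_mode = "magnitude", lfdr_threshold = 0.2,
                           diss_variant = "sqrt", k_taxa = 10, k_range = 2:10,
                           knn_k = 3, diss_cutoff = 0.85, dmm_k_max = 7) {
  list(seed = seed, assoc_threshold = assoc_threshold,
       threshold_mode = threshold_mode, lfdr_threshold = lfdr_threshold,
       diss_variant = diss_variant, k_taxa = k_taxa, k_range = k_range,
       knn_k = knn_k, diss_cutoff = diss_cutoff, dmm_k_max = dmm_k_max)
}

combo_row <- function(task, route, zero, norm, assoc, sparsifier, algorithm) {
  data.frame(task = task, route = route, zero = zero, norm = norm,
             assoc = assoc, sparsifier = sparsifier, algorithm = algorithm,
             stringsAsFactors = FALSE)
}

assoc_rows_dissimilarity <- function() {
  rbind(combo_row(NA, "dissimilarity", "pseudo", "clr", "pearson", NA, NA),
        combo_row(NA, "dissimilarity", "pseudo", "vst", "pearson", NA, NA),
        combo_row(NA, "dissimilarity", "none", "mclr", "pearson", NA, NA),
        combo_row(NA, "dissimilarity", "pseudo", "clr", "spearman", NA, NA),
        combo_row(NA, "dissimilarity", "pseudo", "vst", "spearman", NA, NA),
        combo_row(NA, "dissimilarity", "none", "mclr", "spearman", NA, NA),
        combo_row(NA, "dissimilarity", "none", "mclr", "latentcor", NA, NA),
        combo_row(NA, "dissimilarity", "pseudo", "clr", "proportionality", NA, NA))
}

assoc_rows_network <- function() {
  out <- NULL
  for (assoc in c("pearson", "spearman"))
    for (nz in list(c("pseudo", "clr"), c("pseudo", "vst"), c("none", "mclr")))
      for (sp in c("ttest", "threshold"))
        out <- rbind(out, combo_row(NA, "network", nz[1], nz[2], assoc, sp, NA))
  rbind(out,
        combo_row(NA, "network", "none", "mclr", "spring", "neighborhood", NA),
        combo_row(NA, "network", "pseudo", "clr", "proportionality", "threshold", NA))
}

diss_rows_samples <- function() {
  rbind(combo_row(NA, "dissimilarity", "pseudo", "clr", "aitchison", NA, NA),
        combo_row(NA, "dissimilarity", "pseudo", "vst", "euclidean", NA, NA),
        combo_row(NA, "dissimilarity", "none", "mclr", "euclidean", NA, NA),
        combo_row(NA, "dissimilarity", "pseudo", "fractions", "ckld", NA, NA),
        combo_row(NA, "dissimilarity", "none", "mclr", "bray-curtis", NA, NA))
}

cross_algorithms <- function(rows, algorithms) {
  out <- rows[rep(seq_len(nrow(rows)), each = length(algorithms)), , drop = FALSE]
  out$algorithm <- rep(algorithms, times = nrow(rows))
  out
}

#' Enumerate the method-combination grid of a research task
#'
#' Task 1 (taxon clustering): 8 association rows x 2 dissimilarity-based
#' cluster algorithms plus 14 network rows x 3 network cluster algorithms
#' = 58 combinations.  Tasks 2 (hub detection) and 3 (differential network
#' analysis): the 14 network rows.  Task 4 (sample clustering): DMM on raw
#' counts, 5 dissimilarity rows x 2 algorithms, and 10 sparsified rows x 2
#' network algorithms = 31 combinations.  Order is deterministic (table
#' row order x algorithm order).
#'
#' @param task 1, 2, 3 or 4.
#' @return data.frame, one row per combination, with a unique `id` column.
#' @export
enumerate_combos <- function(task) {
  stopifnot(task %in% 1:4)
  grid <- switch(as.character(task),
    "1" = rbind(
      cross_algorithms(assoc_rows_dissimilarity(), c("hierarchical", "spectral")),
      cross_algorithms(assoc_rows_network(),
                       c("fastgreedy", "louvain", "signed_diffusion"))),
    "2" = ,
    "3" = { g <- assoc_rows_network(); g$algorithm <- NA_character_; g },
    "4" = {
      d <- diss_rows_samples()
      net <- d[rep(seq_len(nrow(d)), each = 2), , drop = FALSE]
      net$route <- "network"
      net$sparsifier <- rep(c("diss-threshold", "knn"), times = nrow(d))
      rbind(combo_row(NA, "count", NA, NA, NA, NA, "dmm"),
            cross_algorithms(d, c("pam", "spectral")),
            cross_algorithms(net, c("fastgreedy", "louvain")))
    })
  grid$task <- task
  grid$id <- apply(grid, 1L, function(r)
    paste(na.omit(c(r[["zero"]], r[["norm"]], r[["assoc"]], r[["sparsifier"]],
                    r[["algorithm"]])), collapse = "|"))
  rownames(grid) <- NULL
  grid
}

#' Reduced method-combination presets
#'
#' Small representative subsets used to study how the number of tried
#' combinations affects the over-optimism bias: 5 of 58 (task 1), 3 of 14
#' (tasks 2 and 3), 5 of 31 (task 4), spread across normalization,
#' association and clustering families.
#'
#' @param task 1, 2, 3 or 4.
#' @return data.frame of combinations (subset of [enumerate_combos()]).
#' @export
reduced_combo_preset <- function(task) {
  full <- enumerate_combos(task)
  ids <- switch(as.character(task),
    "1" = c("pseudo|clr|pearson|hierarchical",
            "none|mclr|spearman|spectral",
            "pseudo|clr|pearson|ttest|fastgreedy",
            "none|mclr|spearman|threshold|louvain",
            "pseudo|clr|proportionality|threshold|signed_diffusion"),
    "2" = ,
    "3" = c("pseudo|clr|pearson|ttest",
            "none|mclr|spearman|threshold",
            "pseudo|clr|proportionality|threshold"),
    "4" = c("dmm",
            "pseudo|clr|aitchison|pam",
            "none|mclr|bray-curtis|spectral",
            "pseudo|vst|euclidean|diss-threshold|fastgreedy",
            "none|mclr|euclidean|knn|louvain"))
  out <- full[full$id %in% ids, , drop = FALSE]
  stopifnot(nrow(out) == length(ids))
  rownames(out) <- NULL
  out
}

# ---- cached building blocks ------------------------------------------------

cache_get <- function(cache, key, fn) {
  if (is.null(cache)) return(fn())
  if (!is.null(cache[[key]])) return(cache[[key]])
  val <- fn()
  cache[[key]] <- val
  val
}

get_normalized <- function(counts, norm, cache = NULL) {
  cache_get(cache, paste0("norm|", norm), function() normalize_counts(counts, norm))
}

get_association <- function(counts, combo, params, cache = NULL) {
  key <- paste("assoc", combo$norm, combo$assoc, sep = "|")
  cache_get(cache, key, function() {
    switch(combo$assoc,
      pearson = ,
      spearman = taxa_correlation(get_normalized(counts, combo$norm, cache), combo$assoc),
      latentcor = latent_correlation(get_normalized(counts, "mclr", cache)),
      proportionality = proportionality(get_normalized(counts, "clr", cache)),
      stop("unknown association: ", combo$assoc))
  })
}

get_sparsified <- function(counts, combo, params, cache = NULL) {
  key <- paste("sparse", combo$norm, combo$assoc, combo$sparsifier, sep = "|")
  cache_get(cache, key, function() {
    if (combo$assoc == "spring")
      return(neighborhood_selection(get_normalized(counts, "mclr", cache),
                                    seed = params$seed))
    R <- get_association(counts, combo, params, cache)
    switch(combo$sparsifier,
      ttest = sparsify_ttest(R, n = ncol(counts), lfdr_threshold = params$lfdr_threshold),
      threshold = sparsify_threshold(R, c = params$assoc_threshold,
                                     mode = params$threshold_mode),
      stop("unknown sparsifier: ", combo$sparsifier))
  })
}

taxa_network_for_combo <- function(counts, combo, params, cache = NULL) {
  rstar <- get_sparsified(counts, combo, params, cache)
  build_network(rstar, variant = params$diss_variant)
}

get_sample_dissimilarity <- function(counts, combo, params, cache = NULL) {
  key <- paste("sdiss", combo$norm, combo$assoc, sep = "|")
  cache_get(cache, key, function() {
    norm <- get_normalized(counts, combo$norm, cache)
    scale_dissimilarity(sample_dissimilarity(norm, combo$assoc))
  })
}

# ---- per-task combo evaluation ---------------------------------------------

n_clusters <- function(labels) length(unique(labels))

#' Evaluate one method combination for taxon clustering (task 1)
#'
#' @param counts count matrix (agglomerated genera x samples).
#' @param taxonomy taxonomy with genus -> family mapping.
#' @param combo one row of the task-1 grid.
#' @param params [default_params()].
#' @param cache optional environment for sharing normalizations and
#'   associations across combinations on the same data.
#' @return list with `value` (ARI against the family categorization),
#'   `labels`, `k`.
#' @export
eval_combo_task1 <- function(counts, taxonomy, combo, params = default_params(),
                             cache = NULL) {
  fam <- stats::setNames(taxonomy$family, taxonomy$taxon_id)[rownames(counts)]
  if (combo$route == "dissimilarity") {
    R <- get_association(counts, combo, params, cache)
    D <- association_to_dissimilarity(R, params$diss_variant)
    labels <- if (combo$algorithm == "hierarchical")
      hierarchical_clustering(D, k = params$k_taxa)
    else
      spectral_clustering(1 - D, k = params$k_taxa, seed = params$seed)
  } else {
    rstar <- get_sparsified(counts, combo, params, cache)
    labels <- switch(combo$algorithm,
      fastgreedy = fast_greedy_modularity(build_network(rstar, params$diss_variant)),
      louvain = louvain_clustering(build_network(rstar, params$diss_variant),
                                   seed = params$seed),
      signed_diffusion = signed_diffusion_clustering(rstar),
      stop("unknown algorithm: ", combo$algorithm))
  }
  names(labels) <- rownames(counts)
  list(value = adjusted_rand_index(labels, fam), labels = labels,
       k = n_clusters(labels))
}

#' Evaluate one method combination for hub detection (task 2)
#'
#' @inheritParams eval_combo_task1
#' @return list with `value` (number of hubs), `hubs`, `centralities`.
#' @export
eval_combo_task2 <- function(counts, combo, params = default_params(),
                             cache = NULL) {
  net <- taxa_network_for_combo(counts, combo, params, cache)
  h <- detect_hubs(net)
  list(value = length(h$hubs), hubs = h$hubs, centralities = h$centralities)
}

#' Evaluate one method combination for differential network analysis
#' (task 3)
#'
#' Networks are built separately for the two strata (e.g. antibiotics vs
#' non-antibiotics samples) and compared with the graphlet correlation
#' distance.
#'
#' @param counts_a,counts_b count matrices of the two strata (same taxa).
#' @inheritParams eval_combo_task1
#' @return list with `value` (GCD between the two group networks).
#' @export
eval_combo_task3 <- function(counts_a, counts_b, combo, params = default_params(),
                             cache_a = NULL, cache_b = NULL) {
  net_a <- taxa_network_for_combo(counts_a, combo, params, cache_a)
  net_b <- taxa_network_for_combo(counts_b, combo, params, cache_b)
  list(value = graphlet_correlation_distance(net_a, net_b))
}

#' Evaluate one method combination for sample clustering (task 4)
#'
#' The ASW is computed on the dissimilarity matrix produced one step
#' before the cluster algorithm (the scaled dissimilarity for PAM and
#' spectral clustering, the sparsified dissimilarity for the network
#' algorithms, and the scaled Bray-Curtis dissimilarity on mclr data for
#' DMM, which clusters raw counts).
#'
#' @inheritParams eval_combo_task1
#' @return list with `value` (ASW), `labels`, `k`.
#' @export
eval_combo_task4 <- function(counts, combo, params = default_params(),
                             cache = NULL) {
  if (combo$algorithm == "dmm") {
    fit <- dmm_fit(counts, k_max = params$dmm_k_max, seed = params$seed)
    bc_combo <- list(norm = "mclr", assoc = "bray-curtis")
    D <- get_sample_dissimilarity(counts, bc_combo, params, cache)
    if (fit$k < 2L) stop("DMM selected a single component; ASW undefined")
    return(list(value = average_silhouette_width(fit$labels, D),
                labels = fit$labels, k = fit$k))
  }
  D <- get_sample_dissimilarity(counts, combo, params, cache)
  if (combo$route == "dissimilarity") {
    sel <- select_k_by_asw(D, algorithm = combo$algorithm,
                           k_range = params$k_range, seed = params$seed)
    return(list(value = sel$asw, labels = sel$labels, k = sel$k))
  }
  dstar <- if (combo$sparsifier == "knn") knn_sparsify(D, K = params$knn_k)
           else diss_threshold_sparsify(D, cutoff = params$diss_cutoff)
  net <- sample_network(dstar)
  labels <- if (combo$algorithm == "fastgreedy") fast_greedy_modularity(net)
            else louvain_clustering(net, seed = params$seed)
  if (n_clusters(labels) < 2L) stop("single community; ASW undefined")
  list(value = average_silhouette_width(labels, dstar), labels = labels,
       k = n_clusters(labels))
}
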