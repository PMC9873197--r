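#' Draw repeated disjoint discovery/validation splits
#'
#' Each repetition draws 2n distinct samples uniformly at random (within
#' strata when given) and splits them into a discovery and a validation
#' set of n samples each.  For stratified plans each set receives exactly
#' n/2 samples per stratum.
#'
#' @param ids sample IDs of the population.
#' @param n samples per set.
#' @param repetitions number of repetitions, default 50.
#' @param strata optional stratum labels (named by or aligned with `ids`);
#'   exactly two strata are supported, as in the antibiotics design.
#' @param seed master seed; per-repetition seeds are derived from it.
#' @return list of split plans (`rep`, `discovery`, `validation`, `seed`).
#' @export
draw_splits <- function(ids, n, repetitions = 50, strata = NULL, seed = 1) {
  old <- .Random.seed_save()
  set.seed(seed)
  rep_seeds <- sample.int(2^30, repetitions)
  if (is.null(strata)) {
    if (2 * n > length(ids))
      stop("need 2n = ", 2 * n, " samples, have ", length(ids))
  } else {
    stopifnot(length(strata) == length(ids))
    if (n %% 2 != 0) stop("stratified splits need even n")
    sizes <- table(strata)
    short <- names(sizes)[sizes < n]
    if (length(short))
      stop("insufficient samples in stratum ", short[1],
           " (need ", n, ", have ", sizes[short[1]], ")")
  }
  plans <- lapply(seq_len(repetitions), function(r) {
    set.seed(rep_seeds[r])
    if (is.null(strata)) {
      chosen <- sample(ids, 2 * n)
      disc <- chosen[seq_len(n)]
      valid <- chosen[n + seq_len(n)]
    } else {
      disc <- valid <- character(0)
      for (s in unique(strata)) {
        pool <- ids[strata == s]
        chosen <- sample(pool, n)
        disc <- c(disc, chosen[seq_len(n / 2)])
        valid <- c(valid, chosen[n / 2 + seq_len(n / 2)])
      }
    }
    list(rep = r, discovery = disc, validation = valid, seed = rep_seeds[r])
  })
  .Random.seed_restore(old)
  plans
}

eval_combo_on_set <- function(task, data, set_ids, combo, params, cache) {
  counts <- data$counts[, set_ids, drop = FALSE]
  switch(as.character(task),
    "1" = eval_combo_task1(counts, data$taxonomy, combo, params, cache),
    "2" = eval_combo_task2(counts, combo, params, cache),
    "3" = {
      st <- data$strata[set_ids]
      lv <- unique(data$strata)
      ca <- counts[, st == lv[1], drop = FALSE]
      cb <- counts[, st == lv[2], drop = FALSE]
      eval_combo_task3(ca, cb, combo, params,
                       cache_a = cache$a, cache_b = cache$b)
    },
    "4" = eval_combo_task4(counts, combo, params, cache))
}

new_task_cache <- function(task) {
  if (task == 3) list(a = new.env(parent = emptyenv()),
                      b = new.env(parent = emptyenv()))
  else new.env(parent = emptyenv())
}

#' Run every method combination on one discovery/validation split
#'
#' All combinations are evaluated on the discovery set; the combination
#' with the maximal criterion value (ARI vs. families, number of hubs,
#' GCD between group networks, or ASW, depending on the task) is selected
#' and re-evaluated on the validation set.  Ties are broken by the
#' centrality-rank rule for hub detection and by enumeration order
#' otherwise.  Combinations that fail on a dataset are recorded and
#' excluded from selection.
#'
#' @param task 1, 2, 3 or 4.
#' @param split one plan from [draw_splits()].
#' @param data list with `counts` (full population), `taxonomy`, and (task
#'   3) `strata`.
#' @param combos combination grid, default [enumerate_combos()] of the
#'   task.
#' @param params [default_params()].
#' @return one-row data.frame with the selected combination, discovery and
#'   validation criterion values, cluster counts and stability measures.
#' @export
run_task_on_split <- function(task, split, data, combos = enumerate_combos(task),
                              params = default_params()) {
  cache_d <- new_task_cache(task)
  evals <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    evals[[i]] <- tryCatch(
      eval_combo_on_set(task, data, split$discovery, combos[i, ], params, cache_d),
      error = function(e) list(value = NA_real_, error = conditionMessage(e)))
  }
  vals <- vapply(evals, function(e) e$value %||% NA_real_, numeric(1))
  n_failed <- sum(is.na(vals))
  if (all(is.na(vals)))
    return(data.frame(rep = split$rep, combo = NA_character_, failed = n_failed,
                      value_discov = NA_real_, value_valid = NA_real_,
                      k_discov = NA_real_, k_valid = NA_real_,
                      ari_stab = NA_real_, jaccard = NA_real_,
                      cosine = NA_real_, stringsAsFactors = FALSE))
  best_val <- max(vals, na.rm = TRUE)
  tied <- which(!is.na(vals) & vals >= best_val - 1e-12)
  best <- if (task == 2 && length(tied) > 1L)
    tied[rank_hub_sets(evals[tied])]
  else tied[1]
  combo <- combos[best, ]
  cache_v <- new_task_cache(task)
  valid_eval <- tryCatch(
    eval_combo_on_set(task, data, split$validation, combo, params, cache_v),
    error = function(e) list(value = NA_real_, error = conditionMessage(e)))
  ari_stab <- jac <- cosine <- NA_real_
  if (task == 1 && !is.null(valid_eval$labels))
    ari_stab <- adjusted_rand_index(evals[[best]]$labels, valid_eval$labels)
  if (task == 2 && !is.null(valid_eval$hubs)) {
    jac <- jaccard_index(evals[[best]]$hubs, valid_eval$hubs)
    cosine <- family_cosine_similarity(evals[[best]]$hubs, valid_eval$hubs,
                                       data$taxonomy)
  }
  data.frame(rep = split$rep, combo = combo$id, failed = n_failed,
             value_discov = vals[best], value_valid = valid_eval$value,
             k_discov = evals[[best]]$k %||% NA_real_,
             k_valid = valid_eval$k %||% NA_real_,
             ari_stab = ari_stab, jaccard = jac, cosine = cosine,
             stringsAsFactors = FALSE)
}

#' Run a full over-optimism experiment
#'
#' Draws `repetitions` disjoint discovery/validation splits of size n each
#' from the population in `data`, runs the combination grid on every
#' split, and returns the per-repetition results.
#'
#' @param data list with `counts`, `taxonomy`, optional `strata` (required
#'   for task 3).
#' @param task 1, 2, 3 or 4.
#' @param n samples per discovery/validation set.
#' @param repetitions number of split repetitions, default 50.
#' @param combos combination grid (defaults to the task's full grid).
#' @param seed master seed.
#' @param params pipeline parameters.
#' @return data.frame, one row per repetition, with attribute "task"/"n".
#' @export
run_overoptimism_experiment <- function(data, task, n, repetitions = 50,
                                        combos = enumerate_combos(task),
                                        seed = 1, params = default_params(seed)) {
  strata <- if (task == 3) {
    if (is.null(data$strata)) stop("task 3 requires data$strata")
    data$strata[colnames(data$counts)]
  } else NULL
  splits <- draw_splits(colnames(data$counts), n, repetitions,
                        strata = strata, seed = seed)
  rows <- lapply(splits, function(sp) run_task_on_split(task, sp, data, combos, params))
  out <- do.call(rbind, rows)
  out$task <- task
  out$n <- n
  out
}

#' Summarize over-optimism across repetitions
#'
#' For each task and n: mean, median and standard deviation of the
#' unscaled difference value_valid - value_discov and of the scaled
#' difference (value_valid - value_discov) / value_discov, plus the effect
#' size mean/sd.  Repetitions with value_discov = 0 are excluded from the
#' scaled statistics and counted.
#'
#' @param results data.frame from [run_overoptimism_experiment()] (rows
#'   from several runs can be concatenated).
#' @return data.frame, one row per task x n.
#' @export
summarize_overoptimism <- function(results) {
  groups <- split(results, list(results$task, results$n), drop = TRUE)
  out <- lapply(groups, function(g) {
    ok <- !is.na(g$value_discov) & !is.na(g$value_valid)
    d <- g$value_valid[ok] - g$value_discov[ok]
    nz <- ok & g$value_discov != 0
    ds <- (g$value_valid[nz] - g$value_discov[nz]) / g$value_discov[nz]
    eff <- function(x) {
      if (length(x) < 2L || stats::sd(x) == 0)
        return(if (length(x) && mean(x) == 0) 0 else NA_real_)
      mean(x) / stats::sd(x)
    }
    data.frame(task = g$task[1], n = g$n[1], repetitions = sum(ok),
               mean_delta = mean(d), median_delta = stats::median(d),
               sd_delta = stats::sd(d), effect_size = eff(d),
               mean_scaled = mean(ds), median_scaled = stats::median(ds),
               sd_scaled = stats::sd(ds), effect_size_scaled = eff(ds),
               n_scaled_excluded = sum(ok) - sum(nz))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$task, out$n), , drop = FALSE]
}

#' Summarize the additional stability measures
#'
#' Task 1: distribution of the ARI between the selected combination's
#' discovery and validation clusterings (ARI_stab).  Task 2: Jaccard index
#' of the hub sets (genus level) and cosine similarity of the family
#' frequency vectors.
#'
#' @param results data.frame from [run_overoptimism_experiment()], tasks 1
#'   or 2.
#' @return data.frame of means/medians/sds per task x n.
#' @export
stability_analysis <- function(results) {
  results <- results[results$task %in% c(1, 2), , drop = FALSE]
  if (!nrow(results)) stop("stability analysis applies to tasks 1 and 2")
  groups <- split(results, list(results$task, results$n), drop = TRUE)
  out <- lapply(groups, function(g) {
    stat <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(c(mean = NA_real_, median = NA_real_, sd = NA_real_))
      c(mean = mean(x), median = stats::median(x),
        sd = if (length(x) > 1) stats::sd(x) else NA_real_)
    }
    a <- stat(g$ari_stab); j <- stat(g$jaccard); co <- stat(g$cosine)
    data.frame(task = g$task[1], n = g$n[1],
               ari_stab_mean = a["mean"], ari_stab_median = a["median"],
               ari_stab_sd = a["sd"],
               jaccard_mean = j["mean"], jaccard_median = j["median"],
               jaccard_sd = j["sd"],
               cosine_mean = co["mean"], cosine_median = co["median"],
               cosine_sd = co["sd"])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$task, out$n), , drop = FALSE]
}

#' Re-run an experiment with a reduced combination grid
#'
#' Identical engine with a subset of the combination grid (defaults to the
#' task's [reduced_combo_preset()]).
#'
#' @inheritParams run_overoptimism_experiment
#' @param subset data.frame of combinations; must be a subset of the
#'   task's full grid.
#' @return summarized over-optimism statistics (see
#'   [summarize_overoptimism()]); the per-repetition results are attached
#'   as attribute "results".
#' @export
reduced_combo_run <- function(data, task, n, repetitions = 50,
                              subset = reduced_combo_preset(task), seed = 1,
                              params = default_params(seed)) {
  if (is.null(subset) || nrow(subset) == 0L) stop("empty combination subset")
  full_ids <- enumerate_combos(task)$id
  if (!all(subset$id %in% full_ids)) stop("subset contains unknown combinations")
  res <- run_overoptimism_experiment(data, task, n, repetitions,
                                     combos = subset, seed = seed, params = params)
  out <- summarize_overoptimism(res)
  attr(out, "results") <- res
  out
}
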