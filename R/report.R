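#' Render an over-optimism summary as a text table
#'
#' One row per n with mean/median/sd of the unscaled and scaled
#' validation-minus-discovery differences and the effect sizes.
#'
#' @param summary data.frame from [summarize_overoptimism()].
#' @return character vector of lines, invisibly printed.
#' @export
report_summary <- function(summary) {
  header <- sprintf("%-5s %-6s %8s %8s %8s %8s | %9s %9s %9s %9s",
                    "task", "n", "mean", "median", "sd", "mean/sd",
                    "mean%", "median%", "sd%", "mean/sd")
  lines <- header
  if (nrow(summary)) {
    pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f%%", 100 * x))
    num <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
    for (i in seq_len(nrow(summary))) {
      s <- summary[i, ]
      lines <- c(lines, sprintf("%-5d %-6d %8s %8s %8s %8s | %9s %9s %9s %9s",
        s$task, s$n, num(s$mean_delta), num(s$median_delta), num(s$sd_delta),
        ifelse(is.na(s$effect_size), "NA", sprintf("%.2f", s$effect_size)),
        pct(s$mean_scaled), pct(s$median_scaled), pct(s$sd_scaled),
        ifelse(is.na(s$effect_size_scaled), "NA",
               sprintf("%.2f", s$effect_size_scaled))))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write a JSON run manifest
#'
#' Records the configuration, master seed and package version so a result
#' file can be regenerated exactly.
#'
#' @param path output path.
#' @param config named list describing the run (task, n, repetitions,
#'   combination ids, synthetic spec, ...).
#' @param seed master seed.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, config, seed) {
  manifest <- list(
    package = "splitbias",
    version = as.character(utils::packageVersion("splitbias")),
    seed = seed,
    config = config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a result table as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_result_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
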