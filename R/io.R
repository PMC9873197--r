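#' Validate a taxa-by-sample count matrix
#'
#' Counts are stored as a plain numeric matrix with taxa in rows and samples
#' in columns; row and column names carry the taxon and sample IDs.
#'
#' @param counts numeric matrix, taxa x samples.
#' @return the matrix, invisibly, after validation.
#' @keywords internal
check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (taxa x samples)")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicated taxon IDs")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample IDs")
  invisible(counts)
}

#' Read a count table from TSV/CSV
#'
#' Expects taxa in rows (first column = taxon ID) and samples in columns
#' (header row of sample IDs).
#'
#' @param path file path.
#' @param sep field separator; `"\t"` for TSV (default), `","` for CSV.
#' @return numeric count matrix, taxa x samples.
#' @export
read_count_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  check_count_matrix(m)
  m
}

#' Write a count table to TSV
#'
#' @param counts count matrix.
#' @param path output path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(taxon_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table from a BIOM file
#'
#' @param path path to a BIOM (JSON or HDF5) file.
#' @return numeric count matrix, taxa x samples.
#' @export
read_biom_counts <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  storage.mode(m) <- "double"
  check_count_matrix(m)
  m
}

#' Read a taxonomy table
#'
#' TSV with columns `taxon_id`, then ranks; must contain `genus` and
#' `family` columns (case-insensitive).
#'
#' @param path file path.
#' @return data.frame with at least columns taxon_id, genus, family.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("taxon_id", "genus", "family") %in% names(df)))
    stop("taxonomy must have columns taxon_id, genus, family")
  df
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `antibiotics`
#' (none-last-year | last-month | other) and optional `age`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  if ("antibiotics" %in% names(df)) {
    bad <- setdiff(unique(df$antibiotics),
                   c("none-last-year", "last-month", "other", NA))
    if (length(bad))
      stop("unknown antibiotics categories: ", paste(bad, collapse = ", "))
  }
  if ("age" %in% names(df) && any(df$age < 0, na.rm = TRUE))
    stop("age must be nonnegative")
  df
}

#' Preprocess a count matrix by depth and prevalence filters
#'
#' Applies, in order: (1) drop samples with sequencing depth (column sum)
#' below `depth_min`; (2) drop taxa present (count > 0) in fewer than
#' `prevalence_min` of the remaining samples; (3) drop remaining samples
#' whose depth is strictly below the empirical `depth_drop_quantile`
#' quantile of the remaining depths (linear-interpolation quantile; ties at
#' the quantile survive). Defaults match a standard gut-microbiome
#' preprocessing pipeline: depth >= 10000, prevalence >= 30%, bottom 10%
#' of depths removed.
#'
#' @param counts count matrix (taxa x samples).
#' @param depth_min minimum sequencing depth, default 10000.
#' @param prevalence_min minimum fraction of samples a taxon must appear in,
#'   default 0.30.
#' @param depth_drop_quantile quantile of remaining depths below which
#'   samples are dropped, default 0.10.
#' @return filtered count matrix with original ID order preserved.
#' @export
preprocess_counts <- function(counts, depth_min = 10000, prevalence_min = 0.30,
                              depth_drop_quantile = 0.10) {
  check_count_matrix(counts)
  stopifnot(depth_min >= 0, prevalence_min >= 0, prevalence_min <= 1,
            depth_drop_quantile >= 0, depth_drop_quantile < 1)
  depths <- colSums(counts)
  keep_s <- depths >= depth_min
  if (!any(keep_s)) stop("preprocessing removed all samples (depth filter)")
  m <- counts[, keep_s, drop = FALSE]
  prev <- rowMeans(m > 0)
  keep_t <- prev >= prevalence_min
  if (!any(keep_t)) stop("preprocessing removed all taxa (prevalence filter)")
  m <- m[keep_t, , drop = FALSE]
  d2 <- colSums(m)
  q <- stats::quantile(d2, depth_drop_quantile, type = 7, names = FALSE)
  m <- m[, d2 >= q, drop = FALSE]
  if (ncol(m) == 0L) stop("preprocessing removed all samples (quantile filter)")
  m
}

#' Agglomerate counts to a taxonomic rank
#'
#' Counts of taxa sharing the same label at `rank` are summed. Taxa with an
#' unknown genus (genus NA, "" or flagged via `unknown_genus`) each keep
#' their own singleton unit, named after the taxon itself.
#'
#' @param counts count matrix (taxa x samples).
#' @param taxonomy data.frame with columns taxon_id, genus, family (and
#'   optionally a logical unknown_genus column).
#' @param rank rank to agglomerate to, e.g. "genus".
#' @return list with elements `counts` (agglomerated matrix) and `taxonomy`
#'   (one row per agglomerated unit, mapping it to its family).
#' @export
agglomerate_to_rank <- function(counts, taxonomy, rank = "genus") {
  check_count_matrix(counts)
  if (!rank %in% names(taxonomy)) stop("rank '", rank, "' missing from taxonomy")
  idx <- match(rownames(counts), taxonomy$taxon_id)
  if (anyNA(idx)) stop("taxa missing from taxonomy: ",
                       paste(utils::head(rownames(counts)[is.na(idx)]), collapse = ", "))
  tax <- taxonomy[idx, , drop = FALSE]
  labels <- as.character(tax[[rank]])
  unknown <- is.na(labels) | labels == ""
  if (rank == "genus" && "unknown_genus" %in% names(tax))
    unknown <- unknown | isTRUE_vec(tax$unknown_genus)
  labels[unknown] <- paste0("unclassified:", rownames(counts)[unknown])
  agg <- rowsum(counts, group = labels, reorder = FALSE)
  fam <- tapply(as.character(tax$family), labels, function(x) x[1])
  out_tax <- data.frame(taxon_id = rownames(agg),
                        genus = rownames(agg),
                        family = as.character(fam[rownames(agg)]),
                        stringsAsFactors = FALSE)
  list(counts = agg, taxonomy = out_tax)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Filter samples by a metadata rule
#'
#' Rules: `"antibiotics-task3"` keeps samples with antibiotics category
#' none-last-year or last-month (the two strata of the differential network
#' task); `"adults-20-65"` keeps samples with age in the closed interval
#' [20, 65].
#'
#' @param counts count matrix (taxa x samples).
#' @param meta metadata data.frame with a sample_id column.
#' @param rule rule name.
#' @return filtered count matrix.
#' @export
filter_samples_by_metadata <- function(counts, meta,
                                       rule = c("antibiotics-task3", "adults-20-65")) {
  rule <- match.arg(rule)
  if (is.null(meta) || nrow(meta) == 0L) stop("empty metadata")
  idx <- match(colnames(counts), meta$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata")
  m <- meta[idx, , drop = FALSE]
  keep <- switch(rule,
    "antibiotics-task3" = m$antibiotics %in% c("none-last-year", "last-month"),
    "adults-20-65" = !is.na(m$age) & m$age >= 20 & m$age <= 65)
  counts[, keep, drop = FALSE]
}
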