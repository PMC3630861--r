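#' Cy3-normalise Cy5 intensities
#'
#' Divides the Cy5 (protein binding) intensity by the Cy3
#' (double-stranding) intensity of the same feature, protein and
#' replicate, cancelling the per-spot double-stranding efficiency.
#'
#' @param table An `intensity_table` (long format).
#' @return data.frame with columns feature_id, protein, replicate,
#'   value (= Cy5/Cy3).
#' @export
normalize_channels <- function(table) {
  tab <- as.data.frame(table)
  cy3 <- tab[tab$channel == "Cy3", c("feature_id", "protein", "replicate", "intensity")]
  cy5 <- tab[tab$channel == "Cy5", c("feature_id", "protein", "replicate", "intensity")]
  names(cy3)[4] <- "cy3"
  names(cy5)[4] <- "cy5"
  merged <- merge(cy5, cy3, by = c("feature_id", "protein", "replicate"),
                  all = TRUE, sort = TRUE)
  orphan <- is.na(merged$cy3) | is.na(merged$cy5)
  if (any(orphan))
    stop(sprintf("missing channel partner for %d row(s), e.g. %s",
                 sum(orphan),
                 paste(utils::head(merged$feature_id[orphan], 3), collapse = ", ")),
         call. = FALSE)
  if (any(merged$cy3 == 0))
    stop(sprintf("zero Cy3 intensity for feature(s) %s",
                 paste(utils::head(merged$feature_id[merged$cy3 == 0], 3),
                       collapse = ", ")), call. = FALSE)
  data.frame(feature_id = merged$feature_id, protein = merged$protein,
             replicate = merged$replicate, value = merged$cy5 / merged$cy3,
             stringsAsFactors = FALSE)
}

#' Summarise normalised replicates to per-core log2 values
#'
#' log2-transforms the normalised values and takes the median per core,
#' pooling technical replicates and (by default) flank variants; with
#' an even count the mean of the two middle values is used (the
#' standard median convention).
#'
#' @param normalized Output of [normalize_channels()].
#' @param design The `probe_design` mapping features to cores.
#' @param per_flank If TRUE, summarise per (core, flank) instead of
#'   pooling flank variants (default FALSE).
#' @return data.frame with columns protein, core_id (and flank_id if
#'   `per_flank`), log2_value.
#' @export
summarize_replicates <- function(normalized, design, per_flank = FALSE) {
  stopifnot(inherits(design, "probe_design"))
  feats <- design$features
  idx <- match(normalized$feature_id, feats$feature_id)
  if (anyNA(idx))
    stop(sprintf("feature(s) not in design: %s",
                 paste(utils::head(unique(normalized$feature_id[is.na(idx)]), 3),
                       collapse = ", ")), call. = FALSE)
  normalized$core_id <- feats$core_id[idx]
  normalized$flank_id <- feats$flank_id[idx]
  keys <- if (per_flank) c("protein", "core_id", "flank_id") else c("protein", "core_id")
  agg <- stats::aggregate(list(log2_value = log2(normalized$value)),
                          by = normalized[keys], FUN = stats::median)
  declared <- unique(feats$core_id)
  for (p in unique(agg$protein)) {
    absent <- setdiff(declared, agg$core_id[agg$protein == p])
    if (length(absent))
      stop(sprintf("no data for declared core(s) %s (protein %s)",
                   paste(utils::head(absent, 3), collapse = ", "), p),
           call. = FALSE)
  }
  agg[order(agg$protein, agg$core_id), , drop = FALSE]
}

#' z-score a vector of per-core log2 summaries
#'
#' z_i = (x_i - median(x)) / sd(x) with the sample (n-1) standard
#' deviation, the array z-score used throughout the analysis.
#'
#' @param summaries Named numeric vector of per-core log2 values
#'   (names = core ids), or a data.frame with columns core_id and
#'   log2_value.
#' @param protein Protein name recorded on the profile.
#' @return Object of class `binding_profile`: `protein`, `entries`
#'   (named numeric vector of z-scores), `n_probes`.
#' @examples
#' zscore_profile(c(a = 0, b = 1, c = 2), "toy")$entries  # -1 0 1
#' @export
zscore_profile <- function(summaries, protein) {
  if (is.data.frame(summaries)) {
    x <- summaries$log2_value
    names(x) <- summaries$core_id
  } else x <- summaries
  if (length(x) < 3L) stop("need at least 3 cores to z-score", call. = FALSE)
  if (anyNA(x)) stop("missing values in log2 summaries", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("constant array: zero standard deviation", call. = FALSE)
  z <- (x - stats::median(x)) / s
  binding_profile(protein, z)
}

#' Construct a binding profile
#'
#' @param protein Protein name.
#' @param entries Named numeric vector mapping core/probe ids to
#'   z-scores.
#' @return Object of class `binding_profile`.
#' @export
binding_profile <- function(protein, entries) {
  if (is.null(names(entries)) || anyNA(entries) || !is.numeric(entries))
    stop("entries must be a complete named numeric vector", call. = FALSE)
  structure(list(protein = protein, entries = entries,
                 n_probes = length(entries)),
            class = "binding_profile")
}

#' @export
print.binding_profile <- function(x, ...) {
  cat(sprintf("Binding profile '%s': %d probes (z range %.2f .. %.2f)\n",
              x$protein, x$n_probes, min(x$entries), max(x$entries)))
  invisible(x)
}

#' Run the full intensity-processing chain
#'
#' ratio (Cy5/Cy3) -> log2 -> median over replicates x flank variants
#' -> z-score over cores, per protein.
#'
#' @param table An `intensity_table`.
#' @param design The matching `probe_design`.
#' @param per_flank Passed to [summarize_replicates()].
#' @return Named list of `binding_profile` objects, one per protein
#'   (per protein x flank if `per_flank`).
#' @export
process_intensities <- function(table, design, per_flank = FALSE) {
  norm <- normalize_channels(table)
  summ <- summarize_replicates(norm, design, per_flank = per_flank)
  if (per_flank)
    summ$protein <- paste(summ$protein, summ$flank_id, sep = ".")
  profs <- lapply(split(summ, summ$protein),
                  function(d) zscore_profile(d, d$protein[1]))
  profs[unique(summ$protein)]
}

#' Convert binding profiles to a wide z-score table
#'
#' @param profiles List of `binding_profile` objects over a common
#'   probe set.
#' @return data.frame: first column `probe`, one numeric column per
#'   protein.
#' @export
zscore_table <- function(profiles) {
  ids <- names(profiles[[1]]$entries)
  out <- data.frame(probe = ids, stringsAsFactors = FALSE)
  for (p in profiles) out[[p$protein]] <- unname(p$entries[ids])
  out
}

#' Write a wide z-score table to TSV
#' @param profiles List of `binding_profile` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zscore_table <- function(profiles, path) {
  utils::write.table(zscore_table(profiles), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Load binding profiles from a wide z-score table
#'
#' Reads a probe x protein table in the layout of a PBM supplementary
#' z-score table: a probe-identifier column followed by one numeric
#' column per protein. The delimiter (tab or comma) is auto-detected
#' from header consistency.
#'
#' @param path TSV or CSV file.
#' @return Named list of `binding_profile` objects, probe order
#'   preserved.
#' @export
load_zscore_table <- function(path) {
  header <- readLines(path, n = 2L)
  if (length(header) < 2L) stop(sprintf("'%s': need a header and data", path), call. = FALSE)
  n_fields <- function(sep) lengths(strsplit(header, sep, fixed = TRUE))
  sep <- if (n_fields("\t")[1] > 1 && length(unique(n_fields("\t"))) == 1) "\t"
         else if (n_fields(",")[1] > 1 && length(unique(n_fields(","))) == 1) ","
         else stop(sprintf("'%s': cannot determine delimiter", path), call. = FALSE)
  message(sprintf("load_zscore_table: using %s as delimiter",
                  if (sep == "\t") "tab" else "comma"))
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE, colClasses = NA)
  if (ncol(tab) < 2L)
    stop(sprintf("'%s': need a probe column plus >=1 protein column", path),
         call. = FALSE)
  probes <- as.character(tab[[1]])
  profs <- list()
  for (j in 2:ncol(tab)) {
    col <- tab[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop(sprintf("'%s': non-numeric value at row %d, column '%s'",
                   path, bad, names(tab)[j]), call. = FALSE)
    }
    z <- col
    names(z) <- probes
    profs[[names(tab)[j]]] <- binding_profile(names(tab)[j], z)
  }
  profs
}
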