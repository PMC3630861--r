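#' Default flanking sequences for probe assembly
#'
#' Four (left, right) flank pairs. Flank f1 reproduces the constant
#' context of the biotinylated kappaB pulldown oligo
#' (AGCTGGGCAT | core | AACTCT); f2-f4 are fixed GC-balanced 10/6-mers.
#'
#' @return data.frame with columns flank_id, left, right.
#' @export
default_flanks <- function() {
  data.frame(
    flank_id = c("f1", "f2", "f3", "f4"),
    left  = c("AGCTGGGCAT", "TGACGTCATG", "CATGAGCTCG", "GTACTGCAGT"),
    right = c("AACTCT", "TGCACA", "ACTGAG", "TCAGTC"),
    stringsAsFactors = FALSE
  )
}

#' Assemble a physical probe design
#'
#' Crosses probe cores with flanking-sequence variants and technical
#' replicates into the full per-feature layout of one array, checking
#' the feature budget.
#'
#' @param cores Character vector of core k-mers (or a `kmer_space`).
#' @param flanks data.frame with columns flank_id, left, right
#'   (default [default_flanks()]).
#' @param replicates Number of technical replicates per probe (default 3).
#' @param capacity Feature budget of the array (default 15000, the
#'   8 x 15K format).
#' @param assignment `"crossed"` (every core gets every flank, the
#'   default) or `"nested"` (flanks cycle across cores).
#' @return Object of class `probe_design`: `cores`, `flanks`,
#'   `replicates`, `capacity`, and `features` — a data.frame with
#'   columns feature_id, core_id, core_seq, flank_id, replicate,
#'   full_seq where full_seq = left + core + right.
#' @examples
#' d <- assemble_probes("GGGAATTTCC", default_flanks()[1, ], replicates = 1)
#' d$features$full_seq  # "AGCTGGGCATGGGAATTTCCAACTCT"
#' @export
assemble_probes <- function(cores, flanks = default_flanks(), replicates = 3L,
                            capacity = 15000L,
                            assignment = c("crossed", "nested")) {
  if (inherits(cores, "kmer_space")) cores <- cores$kmers
  assignment <- match.arg(assignment)
  stopifnot(is.data.frame(flanks),
            all(c("flank_id", "left", "right") %in% names(flanks)),
            replicates >= 1L, capacity >= 1L)
  replicates <- as.integer(replicates)
  n_flank_per_core <- if (assignment == "crossed") nrow(flanks) else 1L
  required <- length(cores) * n_flank_per_core * replicates
  if (required > capacity)
    stop(sprintf("design exceeds array capacity: %d features required, %d available",
                 required, capacity), call. = FALSE)
  if (length(cores) == 0L) {
    features <- data.frame(feature_id = character(0), core_id = character(0),
                           core_seq = character(0), flank_id = character(0),
                           replicate = integer(0), full_seq = character(0),
                           stringsAsFactors = FALSE)
    return(structure(list(cores = character(0), flanks = flanks,
                          replicates = replicates, capacity = as.integer(capacity),
                          assignment = assignment, features = features),
                     class = "probe_design"))
  }
  core_id <- sprintf("c%04d", seq_along(cores))
  if (assignment == "crossed") {
    grid <- expand.grid(replicate = seq_len(replicates),
                        flank = seq_len(nrow(flanks)),
                        core = seq_along(cores),
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[order(grid$core, grid$flank, grid$replicate), ]
  } else {
    flank_of_core <- ((seq_along(cores) - 1L) %% nrow(flanks)) + 1L
    grid <- expand.grid(replicate = seq_len(replicates),
                        core = seq_along(cores),
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[order(grid$core, grid$replicate), ]
    grid$flank <- flank_of_core[grid$core]
  }
  features <- data.frame(
    feature_id = sprintf("F%06d", seq_len(nrow(grid))),
    core_id = core_id[grid$core],
    core_seq = cores[grid$core],
    flank_id = flanks$flank_id[grid$flank],
    replicate = as.integer(grid$replicate),
    full_seq = paste0(flanks$left[grid$flank], cores[grid$core],
                      flanks$right[grid$flank]),
    stringsAsFactors = FALSE
  )
  rownames(features) <- NULL
  structure(list(cores = cores, flanks = flanks, replicates = replicates,
                 capacity = as.integer(capacity), assignment = assignment,
                 features = features),
            class = "probe_design")
}

#' @export
print.probe_design <- function(x, ...) {
  cat(sprintf("Probe design: %d cores x %d flanks x %d replicates = %d features (capacity %d)\n",
              length(x$cores), nrow(x$flanks), x$replicates,
              nrow(x$features), x$capacity))
  invisible(x)
}

#' Write a probe design to a TSV file
#'
#' Tab-separated with header, one row per feature. In addition to the
#' six layout columns, flank_left and flank_right are stored so the
#' design round-trips exactly through [read_design()].
#'
#' @param design A `probe_design`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "probe_design"))
  feats <- design$features
  fl <- design$flanks
  idx <- match(feats$flank_id, fl$flank_id)
  out <- cbind(feats,
               flank_left = fl$left[idx],
               flank_right = fl$right[idx],
               stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a probe design from a TSV file
#'
#' Requires columns feature_id, core_id, core_seq, flank_id, replicate,
#' full_seq. Flank sequences are taken from flank_left/flank_right
#' columns when present, otherwise inferred from the full sequences.
#'
#' @param path TSV file written by [write_design()] (or equivalent).
#' @param capacity Feature budget to record (default 15000).
#' @return A `probe_design`.
#' @export
read_design <- function(path, capacity = 15000L) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stop(sprintf("cannot parse design file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  needed <- c("feature_id", "core_id", "core_seq", "flank_id", "replicate", "full_seq")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop(sprintf("design file '%s' is missing column(s): %s (line 1)",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  core_first <- !duplicated(tab$core_id)
  cores <- tab$core_seq[core_first]
  flank_ids <- unique(tab$flank_id)
  if (all(c("flank_left", "flank_right") %in% names(tab))) {
    fi <- match(flank_ids, tab$flank_id)
    flanks <- data.frame(flank_id = flank_ids,
                         left = tab$flank_left[fi],
                         right = tab$flank_right[fi],
                         stringsAsFactors = FALSE)
  } else {
    flanks <- do.call(rbind, lapply(flank_ids, function(fid) {
      rows <- tab[tab$flank_id == fid, ]
      lens <- nchar(rows$full_seq) - nchar(rows$core_seq)
      # left flank length: position of the core within the full sequence
      starts <- mapply(function(f, c) regexpr(c, f, fixed = TRUE)[1],
                       rows$full_seq, rows$core_seq)
      left_len <- min(starts) - 1L
      data.frame(flank_id = fid,
                 left = substr(rows$full_seq[1], 1L, left_len),
                 right = substr(rows$full_seq[1], left_len + nchar(rows$core_seq[1]) + 1L,
                                nchar(rows$full_seq[1])),
                 stringsAsFactors = FALSE)
    }))
  }
  bad <- which(tab$full_seq != paste0(flanks$left[match(tab$flank_id, flanks$flank_id)],
                                      tab$core_seq,
                                      flanks$right[match(tab$flank_id, flanks$flank_id)]))
  if (length(bad))
    stop(sprintf("design file '%s': full_seq inconsistent with flank+core at line %d",
                 path, bad[1] + 1L), call. = FALSE)
  feats <- tab[, needed]
  feats$replicate <- as.integer(feats$replicate)
  rownames(feats) <- NULL
  structure(list(cores = cores, flanks = flanks,
                 replicates = max(feats$replicate),
                 capacity = as.integer(capacity),
                 assignment = if (length(unique(tab$flank_id[tab$core_id == tab$core_id[1]])) > 1L)
                   "crossed" else "nested",
                 features = feats),
            class = "probe_design")
}
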