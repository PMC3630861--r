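# align a list of binding profiles on a common probe order, erroring
# with the symmetric difference when probe sets disagree
.profile_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  ref <- names(profiles[[1]]$entries)
  for (p in profiles[-1]) {
    ids <- names(p$entries)
    if (!setequal(ids, ref)) {
      diff <- c(utils::head(setdiff(ref, ids), 3), utils::head(setdiff(ids, ref), 3))
      stop(sprintf("profiles cover different probe sets; symmetric difference: %s",
                   paste(diff, collapse = ", ")), call. = FALSE)
    }
  }
  m <- vapply(profiles, function(p) unname(p$entries[ref]), numeric(length(ref)))
  rownames(m) <- ref
  colnames(m) <- unname(vapply(profiles, `[[`, character(1), "protein"))
  m
}

#' Pairwise Pearson correlation of binding profiles
#'
#' @param profiles List of >= 2 `binding_profile` objects over an
#'   identical probe set.
#' @return Object of class `correlation_matrix`: `proteins` and
#'   `values`, a symmetric matrix with unit diagonal.
#' @export
correlation_matrix <- function(profiles) {
  m <- .profile_matrix(profiles)
  if (any(apply(m, 2, stats::sd) == 0))
    stop("profile with zero variance", call. = FALSE)
  v <- stats::cor(m, method = "pearson")
  structure(list(proteins = colnames(m), values = v),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise Pearson correlations of binding profiles:\n")
  print(round(x$values, digits))
  invisible(x)
}

#' Hierarchically cluster binding profiles
#'
#' Agglomerative clustering of the protein z-score vectors with
#' complete linkage; Euclidean distance by default, correlation
#' distance (1 - r) as an option.
#'
#' @param profiles List of >= 2 `binding_profile` objects.
#' @param distance `"euclidean"` (default) or `"correlation"`.
#' @return Object of class `profile_dendrogram`: `hclust` (the stats
#'   fit), `merge`, `heights`, `leaf_order` (protein names in dendrogram
#'   order), `distance`.
#' @export
cluster_profiles <- function(profiles, distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  m <- .profile_matrix(profiles)
  d <- if (distance == "euclidean") stats::dist(t(m))
       else stats::as.dist(1 - stats::cor(m))
  hc <- stats::hclust(d, method = "complete")
  structure(list(hclust = hc, merge = hc$merge, heights = hc$height,
                 leaf_order = hc$labels[hc$order], distance = distance),
            class = "profile_dendrogram")
}

#' @export
print.profile_dendrogram <- function(x, ...) {
  cat(sprintf("Complete-linkage dendrogram (%s distance); leaf order: %s\n",
              x$distance, paste(x$leaf_order, collapse = ", ")))
  invisible(x)
}

#' Leaf that joins the dendrogram last
#'
#' The most distant profile: the singleton absorbed at the highest
#' merge, if the final merge involves one (otherwise the singleton of
#' the highest merge that has one).
#'
#' @param dendro A `profile_dendrogram`.
#' @return Protein name, or NA if no merge absorbs a singleton.
#' @export
outermost_leaf <- function(dendro) {
  mg <- dendro$merge
  for (i in rev(seq_len(nrow(mg)))) {
    leaves <- mg[i, ][mg[i, ] < 0]
    if (length(leaves)) return(unname(dendro$hclust$labels[-leaves[1]]))
  }
  NA_character_
}

#' Write a dendrogram in newick format
#'
#' Converts the complete-linkage tree to a phylo object (branch lengths
#' derived from merge heights) and writes newick.
#'
#' @param dendro A `profile_dendrogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendro, path) {
  phy <- ape::as.phylo(dendro$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Heat-map ordering of a z-score matrix
#'
#' Columns follow the dendrogram leaf order; rows (probes) are sorted
#' by mean z-score, descending. Rendering is left to the caller (e.g.
#' `pheatmap` on the returned matrix).
#'
#' @param profiles List of `binding_profile` objects.
#' @param dendro A `profile_dendrogram` over the same proteins.
#' @return List: `matrix` (probes x proteins, reordered), `row_order`,
#'   `col_order`.
#' @export
heatmap_matrix <- function(profiles, dendro = NULL) {
  m <- if (length(profiles) >= 2L) .profile_matrix(profiles)
       else matrix(profiles[[1]]$entries, ncol = 1,
                   dimnames = list(names(profiles[[1]]$entries),
                                   profiles[[1]]$protein))
  col_order <- if (is.null(dendro)) colnames(m) else dendro$leaf_order
  stopifnot(setequal(col_order, colnames(m)))
  row_order <- rownames(m)[order(rowMeans(m), decreasing = TRUE)]
  list(matrix = m[row_order, col_order, drop = FALSE],
       row_order = row_order, col_order = col_order)
}

#' Top-N binding cores of a profile
#'
#' The core k-mers of the `n` highest z-scores; ties at the cutoff are
#' broken lexicographically by core sequence so the result is
#' deterministic.
#'
#' @param profile A `binding_profile` keyed by core_id.
#' @param design The `probe_design` mapping core ids to sequences.
#' @param n Number of cores (default 20).
#' @return Character vector of n core k-mers, best first.
#' @export
top_n_probes <- function(profile, design, n = 20L) {
  stopifnot(inherits(profile, "binding_profile"), inherits(design, "probe_design"))
  z <- profile$entries
  if (n < 1L || n > length(z))
    stop(sprintf("n must be between 1 and %d", length(z)), call. = FALSE)
  core_map <- design$features$core_seq[match(names(z), design$features$core_id)]
  if (anyNA(core_map))
    stop("profile core ids not found in design", call. = FALSE)
  ord <- order(-z, core_map, method = "radix")
  core_map[ord][seq_len(n)]
}

#' Position frequency matrix and information content of k-mers
#'
#' Exact base frequencies (no pseudocounts) at each position of a set
#' of equal-length k-mers, with per-position information content
#' IC_j = 2 + sum_b f_bj log2 f_bj (bits, 0 log 0 = 0).
#'
#' @param kmers Character vector of equal-length DNA strings.
#' @param protein Optional name recorded on the barcode.
#' @return Object of class `barcode`: `protein`, `top_kmers`, `pfm`
#'   (4 x k, rows A,C,G,T, columns summing to 1), `information_content`.
#' @export
position_frequency_matrix <- function(kmers, protein = NA_character_) {
  if (length(kmers) < 1L) stop("need at least one k-mer", call. = FALSE)
  L <- unique(nchar(kmers))
  if (length(L) != 1L) stop("k-mers must have equal length", call. = FALSE)
  mat <- matrix(unlist(strsplit(kmers, ""), use.names = FALSE),
                nrow = length(kmers), byrow = TRUE)
  pfm <- vapply(seq_len(L), function(j) {
    counts <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    as.numeric(counts) / length(kmers)
  }, numeric(4))
  rownames(pfm) <- c("A", "C", "G", "T")
  colnames(pfm) <- seq_len(L)
  ic <- apply(pfm, 2, function(f) {
    2 + sum(ifelse(f > 0, f * log2(f), 0))
  })
  structure(list(protein = protein, top_kmers = kmers, pfm = pfm,
                 information_content = ic),
            class = "barcode")
}

#' @export
print.barcode <- function(x, ...) {
  cat(sprintf("Barcode%s: %d k-mers of width %d, total IC %.2f bits\n",
              if (is.na(x$protein)) "" else sprintf(" '%s'", x$protein),
              length(x$top_kmers), ncol(x$pfm), sum(x$information_content)))
  invisible(x)
}

#' Half-site symmetry score of a barcode
#'
#' Compares the 5' GG and 3' CC half-site signatures of the kappaB
#' motif: s_left = product of G frequencies over `left_positions`,
#' s_right = product of C frequencies over `right_positions`; the score
#' is min/max of the two (1 when both are 0). 1 = fully symmetric,
#' 0 = one half-site signature absent.
#'
#' @param barcode A `barcode`.
#' @param left_positions Positions of the 5' G signature (default 2:3
#'   for the 11-mer kappaB consensus).
#' @param right_positions Positions of the 3' C signature (default 9:10).
#' @return Real in [0, 1].
#' @export
half_site_symmetry <- function(barcode, left_positions = c(2L, 3L),
                               right_positions = c(9L, 10L)) {
  stopifnot(inherits(barcode, "barcode"))
  k <- ncol(barcode$pfm)
  if (any(c(left_positions, right_positions) < 1L) ||
      any(c(left_positions, right_positions) > k))
    stop(sprintf("positions must lie in 1..%d", k), call. = FALSE)
  s_left <- prod(barcode$pfm["G", left_positions])
  s_right <- prod(barcode$pfm["C", right_positions])
  if (s_left == 0 && s_right == 0) return(1)
  min(s_left, s_right) / max(s_left, s_right)
}

#' Write a barcode in minimal MEME motif format
#'
#' Letter-probability matrix block plus the standard MEME header.
#'
#' @param barcode A `barcode`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(barcode, path) {
  stopifnot(inherits(barcode, "barcode"))
  con <- file(path, "w")
  on.exit(close(con))
  name <- if (is.na(barcode$protein)) "barcode" else barcode$protein
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(barcode$pfm), length(barcode$top_kmers))), con)
  writeLines(apply(barcode$pfm, 2, function(f)
    sprintf(" %.6f %.6f %.6f %.6f", f[1], f[2], f[3], f[4])), con)
  invisible(path)
}

#' Write a correlation matrix to TSV
#' @param cm A `correlation_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlations <- function(cm, path) {
  stopifnot(inherits(cm, "correlation_matrix"))
  out <- data.frame(protein = cm$proteins, cm$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
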