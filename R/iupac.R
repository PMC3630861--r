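#' IUPAC nucleotide degeneracy codes
#'
#' Named list mapping each IUPAC code to the DNA bases it stands for.
#'
#' @format Named list of character vectors.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Construct a degenerate motif
#'
#' Validates an IUPAC consensus string and records its per-position
#' degeneracies. The default consensus is the expanded kappaB 11-mer
#' used throughout the package.
#'
#' @param consensus IUPAC consensus string (characters among
#'   A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @return An object of class `degenerate_motif` with elements
#'   `consensus`, `length`, `degeneracy` (per-position counts) and
#'   `space_size` (product of degeneracies).
#' @examples
#' degenerate_motif("RGGRNNHHYYB")$space_size  # 6912
#' @export
degenerate_motif <- function(consensus) {
  if (!is.character(consensus) || length(consensus) != 1L || nchar(consensus) == 0L)
    stop("`consensus` must be a single non-empty string", call. = FALSE)
  chars <- strsplit(toupper(consensus), "")[[1]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad))
    stop(sprintf("invalid IUPAC character '%s' at position %d of '%s'",
                 chars[bad[1]], bad[1], consensus), call. = FALSE)
  deg <- vapply(chars, function(ch) length(IUPAC_CODES[[ch]]), integer(1))
  structure(
    list(consensus = paste(chars, collapse = ""),
         length = length(chars),
         degeneracy = unname(deg),
         space_size = prod(deg)),
    class = "degenerate_motif"
  )
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat(sprintf("Degenerate motif %s (%d nt, k-mer space size %d)\n",
              x$consensus, x$length, x$space_size))
  invisible(x)
}

#' Expand an IUPAC consensus into its k-mer space
#'
#' Enumerates every DNA string matching the consensus position-wise,
#' each exactly once, in lexicographic order.
#'
#' @param motif A `degenerate_motif`, or a consensus string which is
#'   passed to [degenerate_motif()].
#' @return An object of class `kmer_space`: list with `motif` and
#'   `kmers` (character vector, lexicographic order).
#' @examples
#' expand_iupac("ACGT")$kmers      # "ACGT"
#' length(expand_iupac("GGRRNNYYCC")$kmers)  # 1024
#' @export
expand_iupac <- function(motif) {
  if (is.character(motif)) motif <- degenerate_motif(motif)
  stopifnot(inherits(motif, "degenerate_motif"))
  chars <- strsplit(motif$consensus, "")[[1]]
  sets <- lapply(chars, function(ch) IUPAC_CODES[[ch]])
  # expand.grid varies the first factor fastest; reverse so the first
  # position is the slowest and the result comes out lexicographic
  grid <- do.call(expand.grid,
                  c(rev(sets), list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  kmers <- do.call(paste0, rev(grid))
  kmers <- sort(kmers, method = "radix")
  stopifnot(length(kmers) == motif$space_size, !anyDuplicated(kmers))
  structure(list(motif = motif, kmers = kmers), class = "kmer_space")
}

#' @export
print.kmer_space <- function(x, ...) {
  cat(sprintf("k-mer space of %s: %d %d-mers\n",
              x$motif$consensus, length(x$kmers), x$motif$length))
  invisible(x)
}

#' Test whether DNA strings match an IUPAC consensus position-wise
#'
#' @param kmers Character vector of DNA strings.
#' @param consensus IUPAC consensus string of the same length.
#' @return Logical vector.
#' @export
matches_consensus <- function(kmers, consensus) {
  motif <- degenerate_motif(consensus)
  chars <- strsplit(motif$consensus, "")[[1]]
  vapply(kmers, function(km) {
    if (nchar(km) != motif$length) return(FALSE)
    b <- strsplit(km, "")[[1]]
    all(mapply(function(base, code) base %in% IUPAC_CODES[[code]], b, chars))
  }, logical(1), USE.NAMES = FALSE)
}

#' Pairwise Hamming distance matrix for equal-length k-mers
#'
#' Counts mismatching positions for every pair. Computed by one-hot
#' encoding and crossproducts so the full matrix for thousands of
#' k-mers is cheap.
#'
#' @param x A `kmer_space` or character vector of equal-length DNA strings.
#' @return Symmetric integer-valued matrix with zero diagonal and the
#'   k-mers as dimnames.
#' @examples
#' hamming_matrix(c("AAA", "TTT"))[1, 2]  # 3
#' @export
hamming_matrix <- function(x) {
  kmers <- if (inherits(x, "kmer_space")) x$kmers else x
  if (!is.character(kmers) || length(kmers) < 1L)
    stop("need at least one k-mer", call. = FALSE)
  L <- nchar(kmers)
  if (length(unique(L)) != 1L)
    stop("k-mers must all have equal length", call. = FALSE)
  L <- L[1]
  mat <- matrix(unlist(strsplit(kmers, ""), use.names = FALSE),
                nrow = length(kmers), ncol = L, byrow = TRUE)
  matches <- matrix(0, length(kmers), length(kmers))
  for (base in c("A", "C", "G", "T")) {
    ind <- (mat == base) * 1
    matches <- matches + tcrossprod(ind)
  }
  D <- L - matches
  dimnames(D) <- list(kmers, kmers)
  D
}
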