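#' Principal coordinate analysis (classical metric MDS)
#'
#' Gower decomposition of a distance matrix: double-centre -1/2 D^2,
#' eigendecompose, and keep positive-eigenvalue axes up to a requested
#' fraction of the positive eigenvalue mass. Coordinates are
#' eigenvectors scaled by the square root of their eigenvalue, so the
#' squared norm of coordinate column j equals eigenvalue j.
#'
#' Negative eigenvalues (possible for non-Euclidean metrics such as
#' Hamming) are dropped; a warning reports the negative mass fraction
#' when it is appreciable.
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal.
#' @param retained_fraction Fraction in (0, 1] of the positive
#'   eigenvalue mass to retain (default 0.9).
#' @return Object of class `pcoa_embedding`: `coordinates`
#'   (points x retained axes), `eigenvalues` (all positive eigenvalues,
#'   non-increasing), `retained_fraction` (achieved fraction),
#'   `negative_mass` (|sum of negative eigenvalues| / sum of positive).
#' @examples
#' D <- as.matrix(dist(cbind(c(0, 1, 2))))
#' pcoa(D)$eigenvalues  # single positive eigenvalue 2
#' @export
pcoa <- function(D, retained_fraction = 0.9) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(D < 0))
    stop("distance matrix must be non-negative", call. = FALSE)
  if (any(abs(diag(D)) > 1e-12))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  if (!is.numeric(retained_fraction) || retained_fraction <= 0 || retained_fraction > 1)
    stop("retained_fraction must be in (0, 1]", call. = FALSE)
  n <- nrow(D)
  A <- -0.5 * D^2
  # double centering: B = (I - 11'/n) A (I - 11'/n)
  rm <- rowMeans(A)
  B <- A - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(A)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- which(eig$values > tol)
  neg_mass <- if (length(pos)) {
    abs(sum(eig$values[eig$values < -tol])) / sum(eig$values[pos])
  } else 0
  if (neg_mass > 0.01)
    warning(sprintf("dropping negative eigenvalues (%.1f%% of positive mass)",
                    100 * neg_mass), call. = FALSE)
  if (!length(pos)) {
    return(structure(list(coordinates = matrix(0, n, 0),
                          eigenvalues = numeric(0),
                          retained_fraction = 1,
                          negative_mass = neg_mass),
                     class = "pcoa_embedding"))
  }
  lambda <- eig$values[pos]
  cum <- cumsum(lambda) / sum(lambda)
  keep <- seq_len(min(which(cum >= retained_fraction - 1e-12)))
  coords <- eig$vectors[, pos[keep], drop = FALSE] %*%
    diag(sqrt(lambda[keep]), nrow = length(keep))
  rownames(coords) <- rownames(D)
  structure(list(coordinates = coords,
                 eigenvalues = lambda,
                 retained_fraction = cum[length(keep)],
                 negative_mass = neg_mass),
            class = "pcoa_embedding")
}

#' @export
print.pcoa_embedding <- function(x, ...) {
  cat(sprintf("PCoA embedding: %d points, %d axes (%.1f%% of positive mass)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$retained_fraction))
  invisible(x)
}

#' Select representative points by seeded k-medoids
#'
#' Picks `k` representatives in the retained principal-coordinate space
#' using k-medoids (PAM build + swap). Tiny instances are solved by
#' exhaustive search; for large point sets the seeded CLARA sampling
#' variant is used. Deterministic for a fixed (embedding, k, seed).
#'
#' Because k-mer spaces are constructed in lexicographic order, PAM's
#' lowest-index tie-breaking resolves medoid ties to the
#' lexicographically smallest k-mer.
#'
#' @param embedding A `pcoa_embedding` (or bare coordinate matrix).
#' @param k Number of representatives, 1 <= k <= number of points.
#' @param seed Integer seed controlling the CLARA subsampling stream.
#' @param exact_max Point count up to which exact PAM is used
#'   (CLARA beyond it).
#' @return Sorted integer vector of k distinct point indices.
#' @export
select_representatives <- function(embedding, k, seed = 1L, exact_max = 2000L) {
  coords <- if (inherits(embedding, "pcoa_embedding")) embedding$coordinates else as.matrix(embedding)
  n <- nrow(coords)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n)
    stop(sprintf("k must be between 1 and %d (got %s)", n, format(k)), call. = FALSE)
  k <- as.integer(k)
  if (k == n) return(seq_len(n))
  if (ncol(coords) == 0L) return(seq_len(k))  # degenerate: all points coincide
  if (choose(n, k) <= 5000) {
    # tiny instances: exhaustive search, exact optimum
    D <- as.matrix(dist(coords))
    best <- NULL; best_obj <- Inf
    for (med in utils::combn(n, k, simplify = FALSE)) {
      obj <- sum(apply(D[, med, drop = FALSE], 1, min))
      if (obj < best_obj) { best_obj <- obj; best <- med }
    }
    idx <- best
  } else if (n <= exact_max) {
    fit <- cluster::pam(coords, k = k, metric = "euclidean",
                        pamonce = 6, keep.diss = FALSE, keep.data = FALSE)
    idx <- fit$id.med
  } else {
    old <- .Random.seed_safe()
    on.exit(.restore_seed(old), add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
    fit <- cluster::clara(coords, k = k, metric = "euclidean",
                          samples = 5L,
                          sampsize = min(n, max(2L * k, k + 200L)),
                          pamLike = TRUE, rngR = TRUE)
    idx <- fit$i.med
  }
  sort(unique(as.integer(idx)))
}

# capture/restore .Random.seed without touching it when unset
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Reconstruct pairwise distances from a PCoA embedding
#'
#' Euclidean distances between the rows of the retained coordinates;
#' for a Euclidean-embeddable input with full positive-mass retention
#' these reproduce the original distances.
#'
#' @param embedding A `pcoa_embedding`.
#' @return Symmetric distance matrix.
#' @export
pcoa_distances <- function(embedding) {
  as.matrix(dist(embedding$coordinates))
}
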