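# Independent brute-force oracles used across the suite. These stay
# deliberately naive: they define expected values, not implementations.

# recursive IUPAC enumeration (depth-first), sorted
enumerate_recursive <- function(consensus) {
  codes <- kappaBarray::IUPAC_CODES
  chars <- strsplit(consensus, "")[[1]]
  rec <- function(i) {
    if (i > length(chars)) return("")
    tails <- rec(i + 1L)
    unlist(lapply(codes[[chars[i]]], function(b) paste0(b, tails)))
  }
  sort(rec(1L))
}

# position-wise Hamming distance of two strings
hamming_pair <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exact k-medoids objective by exhaustive search over medoid subsets
brute_force_kmedoids <- function(coords, k) {
  D <- as.matrix(dist(coords))
  best <- Inf
  for (med in utils::combn(nrow(D), k, simplify = FALSE)) {
    obj <- sum(apply(D[, med, drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

kmedoids_objective <- function(coords, medoids) {
  D <- as.matrix(dist(coords))
  sum(apply(D[, medoids, drop = FALSE], 1, min))
}

# naive O(n^3) agglomerative complete-linkage: returns sorted merge heights
brute_force_complete_linkage_heights <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(D[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# two-pass arithmetic z-score oracle
zscore_oracle <- function(x) {
  s <- sort(x)
  n <- length(x)
  med <- if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  sdv <- sqrt(sum((x - mean(x))^2) / (n - 1))
  (x - med) / sdv
}

# shared miniature end-to-end fixture (32 cores x 2 flanks x 3 reps)
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(kappaBarray::make_fixtures(seed = 42L))
    cache
  }
})
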