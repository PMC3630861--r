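#' Construct an energy PWM
#'
#' A log-odds scoring matrix over A,C,G,T plus a chemical potential mu.
#' A window's score is the sum of the matrix entries for its bases;
#' occupancy of a window is logistic(score - mu) (two-state Boltzmann).
#'
#' @param name Protein/dimer name.
#' @param matrix 4 x width numeric matrix, rows named A,C,G,T.
#' @param mu Chemical potential on the score scale. Default places mu
#'   two score units below the best attainable window score, so the
#'   consensus site is strongly but not saturatingly bound.
#' @return Object of class `energy_pwm`.
#' @export
energy_pwm <- function(name, matrix, mu = NULL) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L) stop("PWM matrix must have 4 rows (A,C,G,T)", call. = FALSE)
  if (is.null(rownames(matrix))) rownames(matrix) <- c("A", "C", "G", "T")
  matrix <- matrix[c("A", "C", "G", "T"), , drop = FALSE]
  if (!all(is.finite(matrix))) stop("PWM matrix must be finite", call. = FALSE)
  if (is.null(mu)) mu <- sum(apply(matrix, 2, max)) - 2
  structure(list(name = name, matrix = matrix, mu = mu,
                 width = ncol(matrix)),
            class = "energy_pwm")
}

#' @export
print.energy_pwm <- function(x, ...) {
  cat(sprintf("Energy PWM '%s': width %d, mu = %.3g\n", x$name, x$width, x$mu))
  invisible(x)
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA strings (A,C,G,T).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# scores of all width-w windows of one strand of one sequence
.window_scores <- function(sequence, pwm) {
  bases <- strsplit(sequence, "")[[1]]
  L <- length(bases)
  w <- pwm$width
  n_win <- L - w + 1L
  idx <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(idx)) stop("sequence contains non-ACGT characters", call. = FALSE)
  # per-position per-column contribution lookup
  vapply(seq_len(n_win), function(s) {
    cols <- seq_len(w)
    sum(pwm$matrix[cbind(idx[s + cols - 1L], cols)])
  }, numeric(1))
}

#' Occupancy of a probe sequence under an energy PWM
#'
#' Sums logistic(score - mu) over every window of both strands, the
#' standard two-state approximation of fractional occupancy summed over
#' binding registers. Bounded by 2 * (L - width + 1).
#'
#' @param sequence DNA string (length >= pwm width), or character vector.
#' @param pwm An `energy_pwm`.
#' @return Numeric occupancy (vectorised over `sequence`).
#' @export
probe_occupancy <- function(sequence, pwm) {
  stopifnot(inherits(pwm, "energy_pwm"))
  short <- nchar(sequence) < pwm$width
  if (any(short))
    stop(sprintf("sequence shorter than PWM width (%d)", pwm$width), call. = FALSE)
  rc <- reverse_complement(sequence)
  vapply(seq_along(sequence), function(i) {
    sc <- c(.window_scores(sequence[i], pwm), .window_scores(rc[i], pwm))
    sum(stats::plogis(sc - pwm$mu))
  }, numeric(1))
}

#' Default four-dimer PWM suite
#'
#' Four energy PWMs emulating the binding specificities of NF-kB-family
#' homodimers on a kappaB-like site:
#'
#' * `nv_p50_like` — symmetric GGG(R)..CCC site, G-tilted centre.
#' * `hs_p52_like` — small perturbation of `nv_p50_like` (closest).
#' * `hs_p50_like` — 5'-indifferent, biased toward a 3' CCCC(T/C)
#'   half-site, so the GG..CC half-site symmetry is degraded.
#' * `relA_like` — A-rich centre, most divergent from `nv_p50_like`.
#'
#' The Frobenius divergence from `nv_p50_like` is ordered
#' p52-like < p50-like < relA-like by construction.
#'
#' @return Named list of four `energy_pwm` objects, width 10.
#' @export
default_dimer_suite <- function() {
  mk <- function(...) {
    m <- rbind(...)
    rownames(m) <- c("A", "C", "G", "T")
    m
  }
  #            1     2     3     4     5     6     7     8     9    10
  nv <- mk(
    A = c( 0.5, -2.5, -2.5,  0.8,  0.2,  0.2,  0.0, -1.0, -3.0, -3.0),
    C = c(-2.0, -2.5, -2.5, -2.0,  0.0,  0.0,  0.3,  1.2,  3.0,  3.0),
    G = c( 2.5,  2.5,  2.5,  1.2,  1.2,  1.2, -2.0, -3.0, -3.0, -3.0),
    T = c(-2.0, -2.5, -2.5, -2.0,  0.0,  0.0,  1.2,  0.6, -1.0, -1.0))
  p52 <- nv
  p52["A", c(1, 4, 5, 7)] <- c(0.6, 1.0, 0.3, 0.1)
  p52["G", c(1, 4, 5, 6)] <- c(2.4, 1.0, 1.1, 1.3)
  p52["C", c(7, 8)] <- c(0.4, 1.3)
  p52["T", c(6, 7, 8)] <- c(-0.1, 1.1, 0.5)
  p50 <- mk(
    A = c(0, 0, 0, 0, 0,  0.0, -1.5, -1.5, -2.5, -2.0),
    C = c(0, 0, 0, 0, 0,  0.8,  2.0,  2.0,  2.5,  2.0),
    G = c(0, 0, 0, 0, 0,  0.0, -2.0, -2.0, -2.5, -2.5),
    T = c(0, 0, 0, 0, 0,  0.0,  0.0,  0.0, -0.5,  1.2))
  relA <- nv
  relA["A", c(1, 4, 5, 6, 7)] <- c(2.5,  3.0,  3.0,  3.0,  0.5)
  relA["G", c(1, 4, 5, 6)]    <- c(0.5, -3.0, -3.0, -3.0)
  relA["C", c(4, 5, 6, 7, 8)] <- c(-3.0, -3.0, -3.0, -1.0,  0.8)
  relA["T", c(4, 5, 6, 7, 8)] <- c(-3.0, -3.0, -3.0,  2.0,  1.5)
  list(
    nv_p50_like = energy_pwm("nv_p50_like", nv),
    hs_p52_like = energy_pwm("hs_p52_like", p52),
    hs_p50_like = energy_pwm("hs_p50_like", p50),
    relA_like   = energy_pwm("relA_like", relA)
  )
}

#' Frobenius distance between two energy PWMs
#' @param a,b `energy_pwm` objects of equal width.
#' @return Non-negative real.
#' @export
pwm_distance <- function(a, b) {
  stopifnot(inherits(a, "energy_pwm"), inherits(b, "energy_pwm"),
            a$width == b$width)
  sqrt(sum((a$matrix - b$matrix)^2))
}
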