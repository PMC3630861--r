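#' Two-channel PBM noise model
#'
#' Parameters of the generative model for simulated intensities. Per
#' feature i and replicate r:
#' \deqn{Cy3 = \gamma \delta_i \epsilon, \quad
#'       Cy5 = \delta_i (\beta_0 + \beta_1 occ_i) \epsilon'}
#' with \eqn{\delta_i ~ LogNormal(0, \sigma_{ds}^2)} drawn once per
#' feature (the double-stranding efficiency of the spot, shared between
#' channels and replicates) and \eqn{\epsilon, \epsilon' ~
#' LogNormal(0, \sigma_{meas}^2)} independent per row. The Cy5/Cy3
#' ratio therefore cancels \eqn{\delta_i} exactly — the Cy3
#' normalisation is the correct correction by construction.
#'
#' @param sigma_meas Log-normal multiplicative measurement sd (default 0.05).
#' @param sigma_ds Per-feature double-stranding efficiency spread (default 0.3).
#' @param beta0 Background Cy5 signal (default 100).
#' @param beta1 Cy5 gain per occupancy unit (default 5000).
#' @param gamma Cy3 gain (default 1000).
#' @param seed Master integer seed.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma_meas = 0.05, sigma_ds = 0.3,
                        beta0 = 100, beta1 = 5000, gamma = 1000,
                        seed = 1L) {
  stopifnot(sigma_meas >= 0, sigma_ds >= 0, beta0 > 0, beta1 > 0, gamma > 0)
  structure(list(sigma_meas = sigma_meas, sigma_ds = sigma_ds,
                 beta0 = beta0, beta1 = beta1, gamma = gamma,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# deterministic substream seed derivation, kept within 32-bit range
.derive_seed <- function(master, index, tag) {
  as.integer((as.double(master) * 1000003 + index * 7919 + tag * 104729) %%
               2147483647)
}

#' Simulate a two-channel PBM intensity table
#'
#' Generates Cy3/Cy5 intensities for every (feature, protein,
#' replicate) of a probe design under PWM-occupancy ground truth and
#' the log-normal noise model. Fully reproducible for a fixed seed;
#' the double-stranding factors, Cy3 noise and Cy5 noise are drawn from
#' separate derived substreams per protein, so changing `sigma_ds`
#' leaves the measurement-noise draws untouched.
#'
#' @param design A `probe_design`.
#' @param pwms Named list of `energy_pwm` objects (one per protein).
#' @param noise A `noise_model`.
#' @return Long-format data.frame (class `intensity_table`) with
#'   columns feature_id, protein, channel ("Cy3"/"Cy5"), replicate,
#'   intensity (strictly positive).
#' @export
simulate_intensities <- function(design, pwms = default_dimer_suite(),
                                 noise = noise_model()) {
  stopifnot(inherits(design, "probe_design"), inherits(noise, "noise_model"))
  feats <- design$features
  if (nrow(feats) == 0L) stop("design has no features", call. = FALSE)
  # occupancy depends only on the probe sequence: compute per unique
  # sequence per protein, not per replicate row
  uniq <- !duplicated(paste(feats$core_id, feats$flank_id))
  spot <- feats[uniq, c("core_id", "flank_id", "full_seq")]
  spot$spot_id <- paste(spot$core_id, spot$flank_id, sep = ":")
  feats$spot_id <- paste(feats$core_id, feats$flank_id, sep = ":")
  n_spot <- nrow(spot)
  reps <- sort(unique(feats$replicate))

  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)

  out <- vector("list", length(pwms))
  for (p in seq_along(pwms)) {
    pwm <- pwms[[p]]
    protein <- if (!is.null(names(pwms)) && nzchar(names(pwms)[p]))
      names(pwms)[p] else pwm$name
    occ_spot <- probe_occupancy(spot$full_seq, pwm)
    occ <- occ_spot[match(feats$spot_id, spot$spot_id)]

    set.seed(.derive_seed(noise$seed, p, 1L))
    delta_spot <- stats::rlnorm(n_spot, 0, noise$sigma_ds)
    delta <- delta_spot[match(feats$spot_id, spot$spot_id)]
    set.seed(.derive_seed(noise$seed, p, 2L))
    eps_cy3 <- stats::rlnorm(nrow(feats), 0, noise$sigma_meas)
    set.seed(.derive_seed(noise$seed, p, 3L))
    eps_cy5 <- stats::rlnorm(nrow(feats), 0, noise$sigma_meas)

    cy3 <- noise$gamma * delta * eps_cy3
    cy5 <- delta * (noise$beta0 + noise$beta1 * occ) * eps_cy5
    out[[p]] <- data.frame(
      feature_id = rep(feats$feature_id, 2L),
      protein = protein,
      channel = rep(c("Cy3", "Cy5"), each = nrow(feats)),
      replicate = rep(feats$replicate, 2L),
      intensity = c(cy3, cy5),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("intensity_table", "data.frame")
  tab
}

#' Write / read a long-format intensity table
#'
#' Tab-separated, columns feature_id, protein, channel, replicate,
#' intensity. The reader tolerates extra columns.
#'
#' @param table An `intensity_table` (or compatible data.frame).
#' @param path File path.
#' @return `path` invisibly (writer); an `intensity_table` (reader).
#' @export
write_intensities <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname write_intensities
#' @export
read_intensities <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "")
  needed <- c("feature_id", "protein", "channel", "replicate", "intensity")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop(sprintf("intensity file '%s' is missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  tab <- tab[, c(needed, setdiff(names(tab), needed))]
  tab$replicate <- as.integer(tab$replicate)
  class(tab) <- c("intensity_table", "data.frame")
  tab
}
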