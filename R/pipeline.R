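#' Build a pipeline run configuration
#'
#' Collects the parameters of a full design -> simulate -> process ->
#' compare/barcode run. Defaults are the study conditions used
#' throughout the package: the expanded kappaB 11-mer consensus, 803
#' representative cores, 4 flank variants, 3 technical replicates on a
#' 15K array, the default four-dimer PWM suite and the default noise
#' model.
#'
#' @param consensus IUPAC consensus (default "RGGRNNHHYYB").
#' @param k Number of representative cores (default 803).
#' @param flanks Flank data.frame (default [default_flanks()]).
#' @param replicates Technical replicates (default 3).
#' @param capacity Array feature budget (default 15000).
#' @param suite Named list of `energy_pwm`s (default
#'   [default_dimer_suite()]).
#' @param sigma_meas,sigma_ds Noise parameters (defaults 0.05, 0.3).
#' @param retained_fraction PCoA mass retained for core selection
#'   (default 0.9).
#' @param subsample Optional size of a seeded subsample of the k-mer
#'   space to embed (NULL = full space); keeps desk-scale runs cheap.
#' @param top_n Barcode depth (default 20).
#' @param seed Mandatory master seed.
#' @param outdir Output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(consensus = "RGGRNNHHYYB", k = 803L,
                       flanks = default_flanks(), replicates = 3L,
                       capacity = 15000L, suite = default_dimer_suite(),
                       sigma_meas = 0.05, sigma_ds = 0.3,
                       retained_fraction = 0.9, subsample = NULL,
                       top_n = 20L, seed, outdir = "results") {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(list(consensus = consensus, k = as.integer(k), flanks = flanks,
                 replicates = as.integer(replicates),
                 capacity = as.integer(capacity), suite = suite,
                 sigma_meas = sigma_meas, sigma_ds = sigma_ds,
                 retained_fraction = retained_fraction,
                 subsample = if (is.null(subsample)) NULL else as.integer(subsample),
                 top_n = as.integer(top_n), seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Scalar fields of [run_config()] can be set in the file; `flanks`
#' may be given as a list of `{flank_id, left, right}` records.
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file is read (e.g. from a
#'   command line).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$flanks))
    vals$flanks <- do.call(rbind, lapply(vals$flanks, as.data.frame))
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Design a representative-core probe array
#'
#' Expands the consensus, embeds (a seeded subsample of) the k-mer
#' space by principal coordinates, selects k representative cores by
#' seeded k-medoids, and assembles the physical design.
#'
#' @param config A `run_config`.
#' @return A `probe_design`; the embedding and k-mer space are attached
#'   as attributes `embedding` and `space`.
#' @export
design_array <- function(config) {
  space <- expand_iupac(config$consensus)
  kmers <- space$kmers
  if (!is.null(config$subsample) && config$subsample < length(kmers)) {
    old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
    set.seed(.derive_seed(config$seed, 1L, 7L))
    kmers <- sort(sample(kmers, config$subsample))
  }
  if (config$k > length(kmers))
    stop(sprintf("k = %d exceeds the %d available k-mers",
                 config$k, length(kmers)), call. = FALSE)
  emb <- pcoa(hamming_matrix(kmers), retained_fraction = config$retained_fraction)
  idx <- select_representatives(emb, config$k, seed = config$seed)
  design <- assemble_probes(kmers[idx], flanks = config$flanks,
                            replicates = config$replicates,
                            capacity = config$capacity)
  attr(design, "embedding") <- emb
  attr(design, "space") <- space
  design
}

#' Run the full PBM analysis pipeline
#'
#' design -> simulate -> process -> compare -> barcode, writing every
#' intermediate artifact plus a manifest (file hashes, seed, package
#' version) under `config$outdir`. Identical config + seed gives
#' byte-identical outputs.
#'
#' @param config A `run_config`.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory results: `design`,
#'   `intensities`, `profiles`, `correlations`, `dendrogram`,
#'   `barcodes`, `symmetry`, `manifest`.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    say("[%s] done in %.1f s", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  paths <- list()
  design <- stage("design", design_array(config))
  say("[design] %d cores x %d flanks x %d replicates = %d features",
      length(design$cores), nrow(design$flanks), design$replicates,
      nrow(design$features))
  paths$design <- file.path(config$outdir, "design.tsv")
  write_design(design, paths$design)

  noise <- noise_model(sigma_meas = config$sigma_meas,
                       sigma_ds = config$sigma_ds, seed = config$seed)
  intens <- stage("simulate", simulate_intensities(design, config$suite, noise))
  paths$intensities <- file.path(config$outdir, "intensities.tsv")
  write_intensities(intens, paths$intensities)

  profiles <- stage("process", process_intensities(intens, design))
  paths$zscores <- file.path(config$outdir, "zscores.tsv")
  write_zscore_table(profiles, paths$zscores)

  corr <- stage("compare", correlation_matrix(profiles))
  paths$correlations <- file.path(config$outdir, "correlations.tsv")
  write_correlations(corr, paths$correlations)
  dendro <- cluster_profiles(profiles)
  paths$dendrogram <- file.path(config$outdir, "dendrogram.nwk")
  write_newick(dendro, paths$dendrogram)

  barcodes <- stage("barcode", lapply(profiles, function(p) {
    position_frequency_matrix(top_n_probes(p, design, config$top_n),
                              protein = p$protein)
  }))
  symmetry <- vapply(barcodes, half_site_symmetry, numeric(1))
  for (nm in names(barcodes)) {
    paths[[paste0("meme_", nm)]] <- file.path(config$outdir,
                                              sprintf("barcode_%s.meme", nm))
    write_meme(barcodes[[nm]], paths[[paste0("meme_", nm)]])
  }
  ic_tab <- data.frame(position = seq_len(ncol(barcodes[[1]]$pfm)),
                       vapply(barcodes, `[[`, numeric(ncol(barcodes[[1]]$pfm)),
                              "information_content"),
                       check.names = FALSE)
  paths$information_content <- file.path(config$outdir, "information_content.tsv")
  utils::write.table(ic_tab, paths$information_content, sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  sym_tab <- data.frame(protein = names(symmetry), symmetry = unname(symmetry))
  paths$symmetry <- file.path(config$outdir, "half_site_symmetry.tsv")
  utils::write.table(sym_tab, paths$symmetry, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")

  manifest <- list(
    seed = config$seed,
    consensus = config$consensus,
    k = config$k,
    package_version = as.character(utils::packageVersion("kappaBarray")),
    outputs = lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  paths$manifest <- file.path(config$outdir, "manifest.yaml")
  yaml::write_yaml(manifest, paths$manifest)
  say("[manifest] %d artifacts written to %s", length(paths), config$outdir)
  invisible(list(design = design, intensities = intens, profiles = profiles,
                 correlations = corr, dendrogram = dendro, barcodes = barcodes,
                 symmetry = symmetry, manifest = manifest))
}

#' Generate the miniature fixture bundle used by the test suite
#'
#' A 32-core x 2-flank x 3-replicate design drawn from a seeded
#' subsample of the kappaB k-mer space, its simulated intensities, and
#' the derived z-score table, written to `dir` (TSV).
#'
#' @param seed Master seed.
#' @param dir Output directory (default tempdir()).
#' @return List with `design`, `intensities`, `profiles` and the file
#'   `paths`.
#' @export
make_fixtures <- function(seed = 42L, dir = tempdir()) {
  cfg <- run_config(k = 32L, flanks = default_flanks()[1:2, ],
                    subsample = 256L, capacity = 15000L, seed = seed,
                    outdir = dir)
  design <- design_array(cfg)
  noise <- noise_model(seed = seed)
  intens <- simulate_intensities(design, cfg$suite, noise)
  profiles <- process_intensities(intens, design)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(design = file.path(dir, "fixture_design.tsv"),
                intensities = file.path(dir, "fixture_intensities.tsv"),
                zscores = file.path(dir, "fixture_zscores.tsv"))
  write_design(design, paths$design)
  write_intensities(intens, paths$intensities)
  write_zscore_table(profiles, paths$zscores)
  list(design = design, intensities = intens, profiles = profiles,
       paths = paths)
}
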