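test_that("simulated tables are complete, positive and seed-reproducible", {
  fx <- fixture_bundle()
  tab <- fx$intensities
  expect_true(all(tab$intensity > 0))
  # complete factorial: features x replicates per protein and channel
  counts <- table(tab$protein, tab$channel)
  expect_true(all(counts == nrow(fx$design$features)))
  tab2 <- simulate_intensities(fx$design, default_dimer_suite(),
                               noise_model(seed = 42L))
  expect_identical(tab, tab2)
  tab3 <- simulate_intensities(fx$design, default_dimer_suite(),
                               noise_model(seed = 43L))
  expect_false(identical(tab$intensity, tab3$intensity))
})

test_that("without noise, Cy5/Cy3 equals the occupancy response exactly", {
  d <- assemble_probes(expand_iupac("RGGRNNHHYYB")$kmers[c(1, 400, 6000)],
                       default_flanks()[1, ], replicates = 2)
  nm <- noise_model(sigma_meas = 0, sigma_ds = 0, seed = 1L)
  suite <- default_dimer_suite()[1]
  tab <- simulate_intensities(d, suite, nm)
  norm <- normalize_channels(tab)
  occ <- probe_occupancy(d$features$full_seq, suite[[1]])
  expected <- (nm$beta0 + nm$beta1 * occ) / nm$gamma
  vals <- norm$value[match(d$features$feature_id, norm$feature_id)]
  expect_equal(vals, expected, tolerance = 1e-12)
  # identical across replicates and strictly increasing in occupancy
  rep_sd <- tapply(vals, d$features$core_id, sd)
  expect_true(all(rep_sd == 0))
  ord <- order(occ)
  expect_true(all(diff((nm$beta0 + nm$beta1 * occ[ord])) >= 0))
})

test_that("the double-stranding factor cancels from normalized profiles", {
  fx <- fixture_bundle()
  suite <- default_dimer_suite()
  prof_ds0 <- process_intensities(
    simulate_intensities(fx$design, suite, noise_model(sigma_ds = 0, seed = 7L)),
    fx$design)
  prof_ds5 <- process_intensities(
    simulate_intensities(fx$design, suite, noise_model(sigma_ds = 0.5, seed = 7L)),
    fx$design)
  for (p in names(prof_ds0)) {
    r <- cor(prof_ds0[[p]]$entries, prof_ds5[[p]]$entries[names(prof_ds0[[p]]$entries)])
    expect_gt(r, 0.999)
  }
})

test_that("different seeds perturb only the noise, not the binding structure", {
  fx <- fixture_bundle()
  suite <- default_dimer_suite()
  p1 <- process_intensities(
    simulate_intensities(fx$design, suite, noise_model(seed = 101L)), fx$design)
  p2 <- process_intensities(
    simulate_intensities(fx$design, suite, noise_model(seed = 202L)), fx$design)
  for (p in names(p1))
    expect_gt(cor(p1[[p]]$entries, p2[[p]]$entries[names(p1[[p]]$entries)]), 0.9)
})

test_that("intensity tables round-trip through TSV and tolerate extra columns", {
  fx <- fixture_bundle()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_intensities(fx$intensities, path)
  back <- read_intensities(path)
  expect_equal(as.data.frame(back), as.data.frame(fx$intensities),
               tolerance = 1e-12)
  tab <- read.delim(path)
  tab$extra <- "x"
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_s3_class(read_intensities(path), "intensity_table")
  expect_error(read_intensities(system.file("DESCRIPTION", package = "kappaBarray")),
               "missing column")
})
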