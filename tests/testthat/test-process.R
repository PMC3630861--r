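test_that("channel normalization divides Cy5 by the matching Cy3", {
  tab <- data.frame(
    feature_id = rep(c("F1", "F2", "F3"), 2),
    protein = "p", channel = rep(c("Cy5", "Cy3"), each = 3),
    replicate = 1L,
    intensity = c(1000, 300, 80, 500, 300, 20))
  norm <- normalize_channels(tab)
  expect_equal(norm$value[match(c("F1", "F2", "F3"), norm$feature_id)],
               c(2, 1, 4))
  # missing partner and zero Cy3 are hard errors naming the feature
  expect_error(normalize_channels(tab[-4, ]), "F1")
  tab$intensity[4] <- 0
  expect_error(normalize_channels(tab), "zero Cy3.*F1")
})

test_that("replicate summarization is the median of log2 values per core", {
  d <- assemble_probes(c("GGGAATTTCC", "GGGGATTCCC"), default_flanks()[1, ],
                       replicates = 3)
  norm <- data.frame(feature_id = d$features$feature_id,
                     protein = "p", replicate = d$features$replicate,
                     value = c(1, 2, 4, 2, 2, 2))
  summ <- summarize_replicates(norm, d)
  expect_equal(summ$log2_value, c(1, 1))  # median(0,1,2); log2(2)
  # even replicate count: mean of the two middle values
  norm2 <- norm[norm$replicate < 3, ]
  summ2 <- summarize_replicates(norm2, d)
  expect_equal(summ2$log2_value[1], mean(c(0, 1)))
  expect_error(summarize_replicates(norm[1:3, ], d), "no data for declared core")
})

test_that("flank variants pool into the probe median unless per_flank is set", {
  d <- assemble_probes("GGGAATTTCC", default_flanks()[1:2, ], replicates = 1)
  norm <- data.frame(feature_id = d$features$feature_id, protein = "p",
                     replicate = 1L, value = c(2, 8))
  expect_equal(summarize_replicates(norm, d)$log2_value, 2)  # median(1, 3)
  perf <- summarize_replicates(norm, d, per_flank = TRUE)
  expect_equal(perf$log2_value, c(1, 3))
})

test_that("z-scoring matches the arithmetic oracle and its exact contracts", {
  expect_equal(unname(zscore_profile(c(a = 0, b = 1, c = 2), "t")$entries),
               c(-1, 0, 1))
  set.seed(13)
  x <- rnorm(10); names(x) <- paste0("c", 1:10)
  prof <- zscore_profile(x, "t")
  expect_equal(unname(prof$entries), zscore_oracle(unname(x)), tolerance = 1e-12)
  expect_equal(median(prof$entries), 0, tolerance = 1e-12)
  expect_equal(sd(prof$entries), 1, tolerance = 1e-12)
  # monotone: z-scoring preserves the ordering of summaries
  expect_identical(order(prof$entries), order(x))
  expect_error(zscore_profile(c(a = 1, b = 1), "t"), "at least 3")
  expect_error(zscore_profile(c(a = 1, b = 1, c = 1), "t"), "zero standard deviation")
})

test_that("every produced profile satisfies median 0 / sd 1 within 1e-9", {
  fx <- fixture_bundle()
  for (p in fx$profiles) {
    expect_lt(abs(median(p$entries)), 1e-9)
    expect_lt(abs(sd(p$entries) - 1), 1e-9)
    expect_equal(p$n_probes, 32)
  }
})

test_that("the processing chain is invariant to per-protein gain rescaling", {
  fx <- fixture_bundle()
  tab <- fx$intensities
  scaled <- tab
  pick <- scaled$protein == "nv_p50_like" & scaled$channel == "Cy5"
  scaled$intensity[pick] <- scaled$intensity[pick] * 37.5
  pick3 <- scaled$protein == "nv_p50_like" & scaled$channel == "Cy3"
  scaled$intensity[pick3] <- scaled$intensity[pick3] * 2.25
  p0 <- process_intensities(tab, fx$design)
  p1 <- process_intensities(scaled, fx$design)
  expect_equal(p1$nv_p50_like$entries, p0$nv_p50_like$entries, tolerance = 1e-9)
})

test_that("wide z-score tables load back as profiles with order preserved", {
  fx <- fixture_bundle()
  profs <- suppressMessages(load_zscore_table(fx$paths$zscores))
  expect_length(profs, 4)
  expect_named(profs, names(fx$profiles))
  for (p in names(profs)) {
    expect_equal(profs[[p]]$entries, fx$profiles[[p]]$entries, tolerance = 1e-6)
    expect_identical(names(profs[[p]]$entries), names(fx$profiles[[p]]$entries))
  }
})

test_that("z-table loading auto-detects delimiters and flags bad cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("probe,p1,p2", "a,0.1,1", "b,-0.2,2", "c,0.3,3"), path)
  expect_message(profs <- load_zscore_table(path), "comma")
  expect_length(profs, 2)
  expect_equal(unname(profs$p1$entries), c(0.1, -0.2, 0.3))
  writeLines(c("probe\tp1", "a\t0.1", "b\toops"), path)
  expect_error(suppressMessages(load_zscore_table(path)), "non-numeric")
})
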