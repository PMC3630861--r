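mk_prof <- function(name, z) binding_profile(name, setNames(z, paste0("c", seq_along(z))))

test_that("correlation matrix has the exact self/negation/symmetry structure", {
  set.seed(2)
  z <- rnorm(20)
  a <- mk_prof("a", z)
  b <- mk_prof("b", -z)
  cc <- mk_prof("c", rnorm(20))
  cm <- correlation_matrix(list(a, b, cc))
  expect_equal(diag(cm$values), c(a = 1, b = 1, c = 1))
  expect_equal(cm$values["a", "b"], -1)
  expect_lt(max(abs(cm$values - t(cm$values))), 1e-12)
  # invariance to affine rescaling of a profile
  cm2 <- correlation_matrix(list(mk_prof("a", 3 * z + 7), b, cc))
  expect_equal(cm2$values, cm$values, tolerance = 1e-12)
  # mismatched probe sets are reported with the offending ids
  bad <- binding_profile("d", c(x1 = 1, x2 = 2))
  expect_error(correlation_matrix(list(a, bad)), "symmetric difference.*x1")
  expect_error(correlation_matrix(list(a, mk_prof("e", rep(0, 20)))),
               "zero variance")
})

test_that("complete-linkage clustering matches the brute-force oracle", {
  set.seed(4)
  for (n_prof in c(3, 4, 6)) {
    profs <- lapply(seq_len(n_prof), function(i) mk_prof(letters[i], rnorm(12)))
    dend <- cluster_profiles(profs)
    m <- sapply(profs, function(p) p$entries)
    oracle <- brute_force_complete_linkage_heights(as.matrix(dist(t(m))))
    expect_equal(dend$heights, oracle, tolerance = 1e-12)
    expect_true(all(diff(dend$heights) >= -1e-12))  # monotone merges
  }
})

test_that("identical profiles merge first at height zero", {
  z <- rnorm(15)
  dend <- cluster_profiles(list(mk_prof("a", z), mk_prof("b", z),
                                mk_prof("c", rnorm(15))))
  expect_equal(dend$heights[1], 0)
  expect_identical(sort(dend$hclust$labels[-dend$merge[1, ]]), c("a", "b"))
  expect_equal(outermost_leaf(dend), "c")
})

test_that("newick export preserves leaves and is parseable", {
  profs <- lapply(1:4, function(i) mk_prof(paste0("p", i), rnorm(10)))
  dend <- cluster_profiles(profs)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(dend, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, paste0("p", 1:4))
})

test_that("heat-map ordering follows the dendrogram and mean z", {
  set.seed(6)
  profs <- lapply(1:3, function(i) mk_prof(paste0("p", i), rnorm(10)))
  dend <- cluster_profiles(profs)
  hm <- heatmap_matrix(profs, dend)
  expect_identical(colnames(hm$matrix), dend$leaf_order)
  expect_true(all(diff(rowMeans(hm$matrix)) <= 1e-12))
  # single profile: rows sorted by z descending
  hm1 <- heatmap_matrix(profs[1])
  expect_true(all(diff(hm1$matrix[, 1]) <= 0))
})

test_that("top-N cores rank by z with lexicographic tie-breaks", {
  d <- assemble_probes(c("GGGAATTTCC", "AGGAATTTCC", "TGGAATTTCC"),
                       default_flanks()[1, ], replicates = 1)
  ids <- unique(d$features$core_id)
  prof <- binding_profile("p", setNames(c(1, 2, 2), ids))
  expect_identical(top_n_probes(prof, d, 1), "AGGAATTTCC")
  expect_identical(top_n_probes(prof, d, 2), c("AGGAATTTCC", "TGGAATTTCC"))
  expect_setequal(top_n_probes(prof, d, 3),
                  c("GGGAATTTCC", "AGGAATTTCC", "TGGAATTTCC"))
  expect_error(top_n_probes(prof, d, 4), "between 1 and 3")
})

test_that("position frequency matrices have exact frequencies and IC", {
  bc <- position_frequency_matrix(rep("AGGAAATTCCC", 20))
  expect_true(all(abs(colSums(bc$pfm) - 1) < 1e-12))
  expect_equal(unname(bc$information_content), rep(2, 11))
  mixed <- position_frequency_matrix(c("AA", "CA", "GA", "TA"))
  expect_equal(unname(mixed$information_content), c(0, 2))
  half <- position_frequency_matrix(c(rep("A", 10), rep("C", 10)))
  expect_equal(unname(half$pfm[, 1]), c(0.5, 0.5, 0, 0))
  expect_equal(unname(half$information_content), 1)
  expect_error(position_frequency_matrix(c("AA", "AAA")), "equal length")
})

test_that("half-site symmetry contrasts the GG and CC signatures", {
  bc <- position_frequency_matrix(rep("AGGAAATTCCC", 20))
  expect_equal(half_site_symmetry(bc), 1)
  # no G at position 2: left signature vanishes
  bc2 <- position_frequency_matrix(rep("AAGAAATTCCC", 20))
  expect_equal(half_site_symmetry(bc2), 0)
  # both signatures absent: defined as 1
  bc3 <- position_frequency_matrix(rep("AAAAAAAAAAA", 20))
  expect_equal(half_site_symmetry(bc3), 1)
  expect_error(half_site_symmetry(bc, right_positions = c(12, 13)), "1..11")
})

test_that("MEME export carries the letter-probability matrix", {
  bc <- position_frequency_matrix(c("ACGT", "AAGT", "ACGG"), protein = "toy")
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(bc, path)
  lines <- readLines(path)
  expect_true(any(grepl("^MOTIF toy$", lines)))
  expect_true(any(grepl("alength= 4 w= 4 nsites= 3", lines)))
  mat_lines <- lines[grep("letter-probability", lines) + 1:4]
  parsed <- do.call(rbind, lapply(strsplit(trimws(mat_lines), " +"), as.numeric))
  expect_equal(parsed, t(unname(bc$pfm)), tolerance = 1e-6)
})
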