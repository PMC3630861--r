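test_that("PCoA recovers collinear and degenerate geometries", {
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  emb <- pcoa(D, retained_fraction = 1)
  expect_length(emb$eigenvalues, 1)
  expect_equal(sort(emb$coordinates[, 1]), c(-1, 0, 1), tolerance = 1e-9)
  # all-zero distances: no positive eigenvalues, empty coordinate set
  emb0 <- pcoa(matrix(0, 4, 4))
  expect_equal(ncol(emb0$coordinates), 0)
  expect_length(emb0$eigenvalues, 0)
  # three equidistant points: two equal positive eigenvalues
  De <- matrix(1, 3, 3) - diag(3)
  embe <- pcoa(De, retained_fraction = 1)
  expect_length(embe$eigenvalues, 2)
  expect_equal(embe$eigenvalues[1], embe$eigenvalues[2], tolerance = 1e-9)
})

test_that("PCoA input contracts are enforced", {
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(pcoa(matrix(c(0, -1, -1, 0), 2, 2)), "non-negative")
  expect_error(pcoa(matrix(1, 2, 2)), "diagonal")
  expect_error(pcoa(matrix(0, 2, 2), retained_fraction = 0), "retained_fraction")
})

test_that("PCoA reconstructs Euclidean-embeddable distances and matches cmdscale", {
  set.seed(3)
  for (rep in 1:5) {
    pts <- matrix(rnorm(7 * 3), 7, 3)
    D <- as.matrix(dist(pts))
    emb <- pcoa(D, retained_fraction = 1)
    expect_lt(max(abs(pcoa_distances(emb) - D)) / max(D), 1e-6)
    # eigenvalues agree with the classical-scaling reference
    ref <- suppressWarnings(cmdscale(D, k = 6, eig = TRUE))
    pos <- ref$eig[ref$eig > max(ref$eig) * 1e-9]
    expect_equal(emb$eigenvalues, pos, tolerance = 1e-8)
    # column j of the coordinates carries eigenvalue j of variance mass
    expect_equal(colSums(emb$coordinates^2), emb$eigenvalues, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("retained_fraction truncates axes by positive-eigenvalue mass", {
  set.seed(5)
  pts <- cbind(rnorm(10, sd = 5), rnorm(10, sd = 1), rnorm(10, sd = 0.2))
  D <- as.matrix(dist(pts))
  full <- pcoa(D, retained_fraction = 1)
  part <- pcoa(D, retained_fraction = 0.8)
  expect_lt(ncol(part$coordinates), ncol(full$coordinates))
  expect_gte(part$retained_fraction, 0.8)
})

test_that("seeded k-medoids returns valid, deterministic, near-optimal medoids", {
  set.seed(9)
  coords <- matrix(rnorm(10), 5, 2)
  # k = n returns everything; k = 1 is the exact medoid
  expect_identical(select_representatives(coords, 5), 1:5)
  med1 <- select_representatives(coords, 1)
  D <- as.matrix(dist(coords))
  expect_equal(sum(D[, med1]), min(colSums(D)))
  # determinism for fixed input/seed
  emb <- pcoa(D, retained_fraction = 1)
  expect_identical(select_representatives(emb, 2, seed = 5),
                   select_representatives(emb, 2, seed = 5))
  expect_error(select_representatives(coords, 0), "between 1 and")
  expect_error(select_representatives(coords, 6), "between 1 and")
})

test_that("k-medoids objective is within 5% of brute force for n <= 8, k <= 3", {
  set.seed(21)
  for (n in 4:8) for (k in 1:3) for (rep in 1:3) {
    coords <- matrix(rnorm(n * 2), n, 2)
    idx <- select_representatives(coords, k, seed = rep)
    expect_length(idx, k)
    expect_lte(kmedoids_objective(coords, idx),
               1.05 * brute_force_kmedoids(coords, k) + 1e-12)
  }
})

test_that("representatives drawn from a k-mer embedding are members of the space", {
  ks <- expand_iupac("GGRRNNYY")
  emb <- suppressWarnings(pcoa(hamming_matrix(ks), 0.9))
  idx <- select_representatives(emb, 25, seed = 1)
  expect_length(unique(idx), 25)
  expect_true(all(ks$kmers[idx] %in% ks$kmers))
})
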