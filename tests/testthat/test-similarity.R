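test_that("difference matrix is the signed outer difference with X-minus-Y top right", {
  x <- fragmentation_spectrum(c(100, 150), 200, spectrum_id = "x")
  y <- fragmentation_spectrum(c(120, 170), 200, spectrum_id = "y")
  dm <- pairwise_difference_matrix(spectrum_pair(x, y))
  expect_equal(dm$D[1, ], c(0, -50, -20, -70))
  expect_equal(dm$D[, 1], c(0, 50, 20, 70))
  expect_equal(dm$D + t(dm$D), matrix(0, 4, 4))  # antisymmetry
  expect_equal(diag(dm$D), rep(0, 4))

  # identical single masses
  x1 <- fragmentation_spectrum(100, 200)
  dm1 <- pairwise_difference_matrix(spectrum_pair(x1, x1))
  expect_equal(dm1$D, matrix(0, 2, 2))
})

test_that("difference counts match the blockwise brute-force definition", {
  x <- fragmentation_spectrum(c(100, 150), 200, spectrum_id = "x")
  y <- fragmentation_spectrum(c(120, 170), 200, spectrum_id = "y")
  dm <- pairwise_difference_matrix(spectrum_pair(x, y))
  cm <- mz_difference_counts(dm, tolerance = 0.01)

  # the interspectral difference -20 occurs twice in the top block
  expect_equal(cm$C[1, 3], 2L)  # 100 - 120
  expect_equal(cm$C[2, 4], 2L)  # 150 - 170
  # top-block diagonal zeros see each other
  expect_equal(cm$C[1, 1], 2L)
  expect_equal(cm$C[2, 2], 2L)
  # every count at least 1 (self-match floor)
  expect_true(all(cm$C >= 1L))

  # saturation: window covering the whole range -> m * (m+n) in top rows
  cm_big <- mz_difference_counts(dm, tolerance = 1000)
  expect_true(all(cm_big$C[1:2, ] == 2L * 4L))
  expect_true(all(cm_big$C[3:4, ] == 2L * 4L))

  # tol = 0: only exact repeats count
  cm0 <- mz_difference_counts(dm, tolerance = 0)
  expect_equal(cm0$C[1, 2], 1L)  # -50 unique in top block
  expect_equal(cm0$C[1, 3], 2L)  # -20 repeated exactly

  expect_error(mz_difference_counts(dm, tolerance = -0.1), "non-negative")

  # brute-force equivalence on a batch of random pairs
  set.seed(101)
  for (rep in 1:10) {
    m <- sample(2:6, 1)
    n <- sample(2:6, 1)
    pr <- random_small_pair(m, n)
    dm <- pairwise_difference_matrix(spectrum_pair(pr$x, pr$y))
    cm <- mz_difference_counts(dm, tolerance = 0.01)
    oracle <- oracle_count_matrix(c(pr$x$mz, pr$y$mz), m, n, 0.01)
    expect_identical(cm$C, oracle$C)
    expect_equal(dm$D, oracle$D)
  }
})

test_that("counts in one block do not depend on the other block's rows of D", {
  set.seed(5)
  pr <- random_small_pair(4, 3)
  dm <- pairwise_difference_matrix(spectrum_pair(pr$x, pr$y))
  cm <- mz_difference_counts(dm, tolerance = 0.01)
  # recompute after corrupting the bottom rows of D (collapsing them to a
  # single repeated value changes their counts): top rows of C unchanged
  dm_bad <- dm
  dm_bad$D[5:7, ] <- 0
  cm_bad <- mz_difference_counts(dm_bad, tolerance = 0.01)
  expect_identical(cm_bad$C[1:4, ], cm$C[1:4, ])
  expect_false(identical(cm_bad$C[5:7, ], cm$C[5:7, ]))
})

test_that("transition matrix row-normalizes counts", {
  C <- matrix(c(2, 1, 2, 1,
                1, 2, 1, 2,
                2, 1, 2, 1,
                1, 2, 1, 2), 4, 4, byrow = TRUE)
  T_ <- transition_matrix(C)
  expect_equal(T_[1, ], c(1/3, 1/6, 1/3, 1/6))
  expect_equal(rowSums(T_), rep(1, 4), tolerance = 1e-12)

  T_u <- transition_matrix(matrix(1, 5, 5))
  expect_equal(T_u, matrix(1/5, 5, 5))

  expect_error(transition_matrix(matrix(0, 2, 2)), "row sum")
})

test_that("stationary distribution satisfies pT = p", {
  # doubly stochastic -> uniform
  T_u <- matrix(1/4, 4, 4)
  expect_equal(stationary_distribution(T_u), rep(1/4, 4))

  # period-2 swap chain: p = (1/2, 1/2) solves pT = p
  T_swap <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(stationary_distribution(T_swap), c(0.5, 0.5))

  # defining property and agreement with long power iteration
  set.seed(21)
  for (rep in 1:10) {
    C <- matrix(sample(1:9, 25, replace = TRUE), 5, 5)
    T_ <- transition_matrix(C)
    p <- stationary_distribution(T_)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_lt(max(abs(drop(p %*% T_) - p)), 1e-8)
    expect_equal(p, oracle_stationary(T_), tolerance = 1e-8)
  }
})

test_that("directed graph Laplacian matches its definition", {
  # symmetric T with uniform p: scaling cancels, L = I - T
  T_s <- matrix(1/3, 3, 3)
  diag(T_s) <- 1/3
  p_u <- rep(1/3, 3)
  expect_equal(directed_graph_laplacian(T_s, p_u), diag(3) - T_s)

  # 2x2 hand computation
  T_swap <- matrix(c(0, 1, 1, 0), 2, 2)
  L <- directed_graph_laplacian(T_swap, c(0.5, 0.5))
  expect_equal(L, matrix(c(1, -1, -1, 1), 2, 2))

  # definition against explicit diagonal matrices on a random chain
  set.seed(33)
  C <- matrix(sample(1:9, 16, replace = TRUE), 4, 4)
  T_ <- transition_matrix(C)
  p <- stationary_distribution(T_)
  L <- directed_graph_laplacian(T_, p)
  L_def <- diag(sqrt(p)) %*% (diag(4) - T_) %*% diag(1 / sqrt(p))
  expect_equal(L, L_def, tolerance = 1e-12)

  # symmetrized Laplacian is positive semi-definite
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-8))

  expect_error(directed_graph_laplacian(T_, c(0, p[-1])), "probability")
})

test_that("similarity matrix is the pseudoinverse of the symmetrized Laplacian", {
  L <- matrix(c(1, -1, -1, 1), 2, 2)
  dec <- similarity_matrix(L, 1, 1)
  expect_equal(dec$S, matrix(c(0.25, -0.25, -0.25, 0.25), 2, 2))

  set.seed(44)
  pr <- random_small_pair(3, 4)
  dec <- pair_similarity(pr$x, pr$y)
  M <- (dec$L + t(dec$L)) / 2
  # Moore-Penrose identities
  expect_lt(max(abs(dec$S %*% M %*% dec$S - dec$S)), 1e-6)
  expect_lt(max(abs(M %*% dec$S %*% M - M)), 1e-6)
  # symmetry and non-negative squared commute distances
  expect_lt(max(abs(dec$S - t(dec$S))), 1e-8)
  d2 <- outer(diag(dec$S), diag(dec$S), "+") - 2 * dec$S
  expect_true(all(d2 >= -1e-8))
  # agreement with the svd pseudoinverse oracle
  expect_equal(dec$S, oracle_pinv(M), tolerance = 1e-8)
  # and with MASS::ginv as a second independent route
  expect_equal(dec$S, MASS::ginv(M), tolerance = 1e-6)
})

test_that("quadrant views tile S and swap consistently under relabeling", {
  set.seed(55)
  pr <- random_small_pair(3, 5)
  dec_xy <- pair_similarity(pr$x, pr$y)
  expect_identical(dim(similarity_quadrant(dec_xy, "xx")), c(3L, 3L))
  expect_identical(dim(similarity_quadrant(dec_xy, "xy")), c(3L, 5L))
  expect_identical(dim(similarity_quadrant(dec_xy, "yy")), c(5L, 5L))
  expect_equal(similarity_quadrant(dec_xy, "yx"),
               t(similarity_quadrant(dec_xy, "xy")), tolerance = 1e-8)
  # swapping the input spectra transposes the interspectral quadrant
  dec_yx <- pair_similarity(pr$y, pr$x)
  expect_equal(similarity_quadrant(dec_yx, "xy"),
               t(similarity_quadrant(dec_xy, "xy")), tolerance = 1e-8)
})

test_that("matrix dump writes one delimited file per stage", {
  pr <- random_small_pair(2, 2)
  dec <- pair_similarity(pr$x, pr$y)
  dir <- withr::local_tempdir()
  paths <- dump_similarity_matrices(dec, dir)
  expect_setequal(basename(paths), c("d.tsv", "c.tsv", "t.tsv", "s.tsv"))
  d_back <- utils::read.table(file.path(dir, "d.tsv"), header = TRUE,
                              sep = "\t")
  expect_equal(unname(as.matrix(d_back)), dec$D, tolerance = 1e-6)
})
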