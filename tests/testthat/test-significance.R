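test_that("sampled permutation plans preserve within-block m/z order", {
  set.seed(301)
  x <- sort(runif(4, 100, 300))
  y <- sort(runif(3, 100, 300))
  concat <- c(x, y)
  for (rep in 1:200) {
    plan <- sample_order_preserving_permutation(concat, 4, 3)
    expect_setequal(plan$perm, 1:7)  # a bijection
    xp <- concat[plan$perm[1:4]]
    yp <- concat[plan$perm[5:7]]
    expect_false(is.unsorted(xp, strictly = TRUE))
    expect_false(is.unsorted(yp, strictly = TRUE))
    # multiset of m/z preserved
    expect_equal(sort(c(xp, yp)), sort(concat))
  }
})

test_that("plan sampling covers all valid assignments uniformly", {
  # m = 1, n = 1: exactly 2 plans, both must occur
  set.seed(302)
  seen <- character()
  for (rep in 1:1000) {
    plan <- sample_order_preserving_permutation(c(100, 200), 1, 1)
    seen <- union(seen, paste(plan$perm, collapse = ","))
  }
  expect_length(seen, 2L)

  # x = (1, 3), y = (2): the 3 distinct plans occur ~uniformly
  concat <- c(1, 3, 2)
  draws <- replicate(3000, paste(
    sample_order_preserving_permutation(concat, 2, 1)$perm, collapse = ","
  ))
  tab <- table(draws)
  expect_length(tab, 3L)
  chi2 <- sum((tab - 1000)^2 / 1000)
  expect_lt(chi2, qchisq(0.999, df = 2))

  # the identity assignment is always among the valid plans
  plans <- all_permutation_plans(concat, 2, 1)
  expect_true(any(vapply(plans, function(p) all(p == 1:3), NA)))
})

test_that("permuted_score matches value-lookup recomputation on all plans", {
  set.seed(303)
  pr <- random_small_pair(2, 2)
  dec <- pair_similarity(pr$x, pr$y)
  concat <- dec$concat_mz

  # identity plan returns the observed score exactly
  id_plan <- structure(list(perm = 1:4, m = 2L, n = 2L),
                       class = "permutation_plan")
  observed <- align_dp(similarity_quadrant(dec, "xy"))$score
  expect_identical(permuted_score(dec, id_plan), observed)

  # all 6 plans: rebuild the quadrant independently by value lookup
  for (perm in all_permutation_plans(concat, 2, 2)) {
    plan <- structure(list(perm = perm, m = 2L, n = 2L),
                      class = "permutation_plan")
    xp_vals <- sort(concat[perm[1:2]])
    yp_vals <- sort(concat[perm[3:4]])
    quad <- matrix(0, 2, 2)
    for (a in 1:2) {
      for (b in 1:2) {
        ia <- which(concat == xp_vals[a])[1]
        ib <- which(concat == yp_vals[b])[1]
        quad[a, b] <- dec$S[ia, ib]
      }
    }
    expect_equal(permuted_score(dec, plan), align_dp(quad)$score,
                 tolerance = 1e-12)
    # symmetric conjugation keeps S symmetric
    Sp <- dec$S[perm, perm]
    expect_equal(Sp, t(Sp), tolerance = 1e-8)
  }

  bad_plan <- structure(list(perm = 1:6, m = 3L, n = 3L),
                        class = "permutation_plan")
  expect_error(permuted_score(dec, bad_plan), "does not match")
})

test_that("p-value follows max(count/k, 1/k) with ties counted", {
  expect_equal(pvalue_from_counts(7, 100), 0.07)
  expect_equal(pvalue_from_counts(0, 1000), 0.001)
  expect_equal(pvalue_from_counts(0, 10), 0.1)
  expect_equal(pvalue_from_counts(100, 100), 1)
  expect_error(pvalue_from_counts(5, 4))
})

test_that("monte_carlo_pvalue respects its contract and early stopping", {
  set.seed(304)
  # a related pair: strong signal drives p to the floor through all stages
  gt <- make_related_pair(block_molecule(c(90.05, 120.1, 150.2, 110.3)),
                          c("2" = 14.01565))
  dec <- pair_similarity(gt$spectrum_a, gt$spectrum_b)
  obs <- align_dp(similarity_quadrant(dec, "xy"))$score
  pv <- monte_carlo_pvalue(dec, obs, seed = 1)
  expect_gte(pv$pvalue, 1 / pv$iterations)
  expect_identical(pv$iterations, length(pv$null_scores))
  expect_identical(pv$pvalue,
                   pvalue_from_counts(sum(pv$null_scores >= obs - 1e-9),
                                      pv$iterations))

  # determinism under a fixed seed
  pv2 <- monte_carlo_pvalue(dec, obs, seed = 1)
  expect_identical(pv$pvalue, pv2$pvalue)
  expect_identical(pv$null_scores, pv2$null_scores)

  # monotone in the observed score for the same seed/nulls
  pv_hi <- monte_carlo_pvalue(dec, obs + 1, seed = 1)
  expect_lte(pv_hi$pvalue, pv$pvalue)

  # an unbeatable observed score reaches the final stage floor
  pv_top <- monte_carlo_pvalue(dec, max(pv$null_scores) + 10, seed = 1)
  expect_equal(pv_top$pvalue, 1 / 1000)
  expect_false(pv_top$stopped_early)

  # a hopeless observed score stops after the second stage with p = 1
  pv_null <- monte_carlo_pvalue(dec, -1, seed = 1)
  expect_identical(pv_null$iterations, 100L)
  expect_true(pv_null$stopped_early)
  expect_equal(pv_null$pvalue, 1)

  # contract errors
  expect_error(monte_carlo_pvalue(dec, Inf, seed = 1), "finite")
  expect_error(monte_carlo_pvalue(dec, obs), "seed")
  expect_error(monte_carlo_pvalue(dec, obs, schedule = c(100, 10), seed = 1),
               "increasing")
})

test_that("null spectrum pairs are rarely called significant", {
  # validity of the test under the null: exchangeable random spectra must
  # not reach p <= 0.05 more than ~5% of the time (conservative is fine)
  set.seed(305)
  n_pairs <- 60
  hits <- 0L
  for (i in seq_len(n_pairs)) {
    a <- random_spectrum(8, spectrum_id = "a")
    b <- random_spectrum(8, spectrum_id = "b")
    ps <- compare_pair(a, b, simile_params(seed = i))
    if (ps$pvalue <= 0.05) hits <- hits + 1L
  }
  expect_lte(hits / n_pairs, 0.07)
})
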