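test_that("layer clustering partitions contiguously with near-equal sizes", {
  even <- cluster_layers(profile_from_r(runif(200)), k = 20)
  expect_true(all(even$n_layers == 10))

  uneven <- cluster_layers(profile_from_r(runif(199)), k = 20)
  expect_equal(uneven$n_layers, c(rep(10L, 19), 9L))

  all_above <- cluster_layers(profile_from_r(rep(0.9, 60)), k = 6)
  expect_true(all(all_above$score == 1))

  expect_error(cluster_layers(profile_from_r(runif(10)), k = 20),
               "defined layers")

  # undefined layers are dropped before clustering and sizes rebalanced
  prof <- profile_from_r(runif(105))
  prof$defined[1:5] <- FALSE
  cl <- cluster_layers(prof, k = 10)
  expect_equal(sum(cl$n_layers), 100L)
  expect_true(all(cl$n_layers == 10))
})

test_that("exact test matches hand-enumerated and degenerate cases", {
  # K = 3, unit cluster sizes, d = (1, -1, 1): sums are +-1+-1+-1
  res <- exact_paired_permutation(paired_cluster_series(
    clusters_from_counts(c(1, 0, 1), c(1, 1, 1)),
    clusters_from_counts(c(0, 1, 0), c(1, 1, 1))))
  expect_equal(res$rank_smallest, 5)
  expect_equal(res$tie_count, 3)
  expect_equal(res$total, 8)
  expect_equal(res$p_upper, 0.25)   # 1 - (5 + (3-1)/2)/8, oracle-checked below
  o <- oracle_permutation(c(1, 0, 1), c(1, 1, 1), c(0, 1, 0), c(1, 1, 1))
  expect_equal(res$p_upper, o$p)

  # identical subjects: every reallocation ties at zero
  same <- clusters_from_counts(c(3, 5, 2, 7), c(10, 10, 10, 10))
  deg <- exact_paired_permutation(paired_cluster_series(same, same))
  expect_equal(deg$rank_smallest, 1)
  expect_equal(deg$tie_count, 2^4)
  expect_equal(deg$p_upper, 1 / 2 - 2^-(4 + 1))

  big <- paired_cluster_series(clusters_from_counts(rep(1, 25), rep(2, 25)),
                               clusters_from_counts(rep(0, 25), rep(2, 25)))
  expect_error(exact_paired_permutation(big), "monte_carlo_permutation")
})

test_that("midpoint tie p-value follows the midrank convention", {
  expect_equal(midpoint_tie_pvalue(1, 1000, 1000), 1 / 2 - 1 / 2000)
  # all-below, unique observed maximum: p is exactly 0
  expect_equal(midpoint_tie_pvalue(1000, 1, 1000), 0)
  expect_error(midpoint_tie_pvalue(0, 1, 10), "rank_smallest")
  expect_error(midpoint_tie_pvalue(5, 7, 10), "tie_count")
})

test_that("exact test agrees with the naive oracle on random rational series", {
  set.seed(20)
  for (i in 1:30) {
    k <- sample(2:10, 1)
    series <- random_series(k)
    res <- exact_paired_permutation(series)
    o <- oracle_permutation(series$m_a, series$n_a, series$m_b, series$n_b)
    expect_equal(res$rank_smallest, o$rank_smallest)
    expect_equal(res$tie_count, o$tie_count)
    expect_equal(res$p_upper, o$p)
    # anti-symmetry of the midrank p-value
    swapped <- exact_paired_permutation(paired_cluster_series(
      clusters_from_counts(series$m_b, series$n_b),
      clusters_from_counts(series$m_a, series$n_a)))
    expect_equal(res$p_upper + swapped$p_upper, 1 - 2^-k)
    # flipping a zero-difference cluster never changes the statistic
    n_zero <- sum(series$m_a / series$n_a == series$m_b / series$n_b)
    expect_equal(res$tie_count %% 2^n_zero, 0)
  }
})

test_that("Monte-Carlo estimate tracks the exact test", {
  set.seed(30)
  series <- paired_cluster_series(
    clusters_from_counts(rbinom(20, 10, 0.6), rep(10, 20)),
    clusters_from_counts(rbinom(20, 10, 0.4), rep(10, 20)))
  ex <- exact_paired_permutation(series)
  mc <- monte_carlo_permutation(series, n_draws = 20000, seed = 8)
  expect_lt(abs(mc$p_upper - ex$p_upper), 3 * max(mc$se, 1e-4))
  expect_identical(tidy(mc),
                   tidy(monte_carlo_permutation(series, n_draws = 20000,
                                                seed = 8)))

  same <- clusters_from_counts(rep(5, 20), rep(10, 20))
  null_mc <- monte_carlo_permutation(paired_cluster_series(same, same),
                                     n_draws = 5000, seed = 1)
  expect_equal(null_mc$p_upper, 0.5, tolerance = 0.01)
  expect_error(monte_carlo_permutation(series, n_draws = 10), ">= 1000")
})

test_that("profile comparison wires clustering into the test", {
  prof <- simulate_layer_profiles(200, frac_above = c(0.9, 0.1), seed = 12)
  pa <- prof[prof$subject == "a", ]
  pb <- prof[prof$subject == "b", ]
  res <- compare_layer_profiles(pa, pb, k = 20, cutoff = 0.05)
  expect_s3_class(res, "perm_test")
  expect_equal(res$total, 2^20)
  expect_lt(res$p_upper, 0.01)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$p_upper, res$p_upper)
  expect_equal(glance(res)$p_two_sided, res$p_two_sided)
})
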