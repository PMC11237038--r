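test_that("sampled structures are valid, Euclidean and seeded", {
  s <- sample_structure(3, dim = 2, seed = 1)
  expect_s3_class(s$dissim, "dissim")
  expect_equal(dim(unclass(s$dissim)), c(3L, 3L))

  expect_identical(unclass(sample_structure(6, seed = 4)$dissim),
                   unclass(sample_structure(6, seed = 4)$dissim))

  d <- unclass(sample_structure(8, seed = 5)$dissim)
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)
  }
})

test_that("noiseless permuted pairs are exact relabelings the pipeline recovers", {
  base <- normalize_dissim(rand_dissim(10, seed = 31))
  pr <- make_pair(base, 0, seed = 32)
  perm <- pr$true_permutation
  expect_true(!anyDuplicated(perm))
  expect_equal(unclass(pr$target)[perm, perm], unclass(base),
               ignore_attr = TRUE)
  expect_identical(dissim_labels(pr$target)[perm], dissim_labels(base))

  sw <- gw_sweep(base, normalize_dissim(pr$target), n_trials = 15, seed = 33)
  mr <- matching_rate(select_optimum(sw)$plan, dissim_labels(base),
                      dissim_labels(pr$target))
  expect_equal(mr$matching_rate, 100)

  still <- make_pair(base, 0, seed = 34, permute = FALSE)
  expect_equal(unclass(still$target), unclass(base), ignore_attr = TRUE)
})

test_that("extreme noise drives matching toward chance", {
  rates <- vapply(1:6, function(s) {
    base <- normalize_dissim(rand_dissim(10, seed = 40 + s))
    pr <- make_pair(base, noise_sd = 25 * mean(base[upper.tri(base)]),
                    seed = 50 + s)
    sw <- gw_sweep(base, normalize_dissim(pr$target), n_trials = 8,
                   seed = 60 + s)
    matching_rate(select_optimum(sw)$plan, dissim_labels(base),
                  dissim_labels(pr$target))$matching_rate
  }, numeric(1))
  # chance is 10%; require the average to be far below perfect recovery
  expect_lt(mean(rates), 35)
})

test_that("category pairs show block structure and carry metadata", {
  pr <- make_category_pair(n_categories = 2, items_per_category = 2,
                           between_sep = 2, within_scale = 0.1,
                           seed = 3, permute = FALSE)
  expect_equal(dim(unclass(pr$source)), c(4L, 4L))
  cats <- pr$params$categories
  src <- unclass(pr$source)
  within <- src[1, 2]
  between <- src[1, 3]
  expect_gt(between, within)
  expect_equal(cats, c(1, 1, 2, 2))

  # within/between scale calibration
  big <- make_category_pair(n_categories = 3, items_per_category = 6,
                            between_sep = 1, within_scale = 0.2, seed = 7,
                            permute = FALSE)
  m <- unclass(big$source)
  cats <- big$params$categories
  same <- outer(cats, cats, "==") & upper.tri(m)
  diff_ <- outer(cats, cats, "!=") & upper.tri(m)
  expect_equal(mean(m[same]), 0.2, tolerance = 1e-6)
  expect_gt(mean(m[diff_]), 3 * mean(m[same]))
})

test_that("resampled fine structure preserves coarse agreement but destroys item identity", {
  pr <- make_category_pair(n_categories = 3, items_per_category = 8,
                           between_sep = 1, within_scale = 0.2,
                           resample_fine = TRUE, seed = 11, permute = FALSE)
  src <- normalize_dissim(pr$source)
  tgt <- normalize_dissim(pr$target)
  expect_gt(rsa_spearman(src, tgt), 0.6)
  expect_gt(max(abs(unclass(src) - unclass(tgt))), 1e-3)

  matched <- make_category_pair(n_categories = 3, items_per_category = 8,
                                resample_fine = FALSE, seed = 11,
                                permute = FALSE)
  expect_equal(unclass(matched$source), unclass(matched$target),
               ignore_attr = TRUE)
})

test_that("rater panels discretize and average back to the base structure", {
  base <- normalize_dissim(rand_dissim(6, seed = 71))

  # noiseless single rater reproduces the rounded scaled matrix exactly
  tb0 <- simulate_rater_panel(base, n_raters = 1, rater_noise_sd = 0,
                              seed = 1)
  d0 <- dissim_from_ratings(tb0, labels = dissim_labels(base))
  expect_equal(unclass(d0), round(7 * unclass(base)), ignore_attr = TRUE)

  # large panels converge on the discretized expectation
  tb <- simulate_rater_panel(base, n_raters = 500, rater_noise_sd = 0.7,
                             seed = 2)
  d <- dissim_from_ratings(tb, labels = dissim_labels(base))
  expect_gt(cor(upper_entries_of(d), upper_entries_of(base)), 0.99)

  expect_false(identical(
    simulate_rater_panel(base, 3, seed = 5)$rating,
    simulate_rater_panel(base, 3, seed = 6)$rating))
  expect_error(simulate_rater_panel(rand_dissim(4, 1), 2), "normalized")
})

test_that("trial-averaged continuous ratings behave like the generating model", {
  base <- normalize_dissim(rand_dissim(6, seed = 81))

  exact <- simulate_llm_trials(base, n_trials = 3, trial_noise_sd = 0,
                               seed = 1)
  expect_equal(unclass(exact), pmin(7 * unclass(base), 7),
               ignore_attr = TRUE)

  # entry variance shrinks like 1/n_trials
  var_at <- function(k) {
    reps <- vapply(1:60, function(s) {
      unclass(simulate_llm_trials(base, n_trials = k, trial_noise_sd = 0.5,
                                  seed = 100 + s))[1, 2]
    }, numeric(1))
    var(reps)
  }
  v1 <- var_at(1)
  v5 <- var_at(5)
  expect_equal(v1 / v5, 5, tolerance = 0.6)
})
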