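test_that("gw_cost agrees with the explicit four-index loop", {
  # uniform outer-product coupling on a 4x4 pair
  D <- rand_dissim(4, seed = 1)
  Dp <- rand_dissim(4, seed = 2)
  G <- matrix(1 / 16, 4, 4)
  expect_equal(gw_cost(D, Dp, G), brute_gw_cost(D, Dp, G), tolerance = 1e-12)

  # random couplings across sizes
  for (seed in 1:6) {
    n <- 3 + seed %% 3
    m <- 4 + seed %% 3
    Da <- rand_dissim(n, seed = 10 + seed)
    Db <- rand_dissim(m, seed = 20 + seed)
    G <- unclass(random_coupling(n, m, seed))
    expect_lt(abs(gw_cost(Da, Db, G) - brute_gw_cost(Da, Db, G)), 1e-10)
  }
})

test_that("gw_cost is zero for perfect self-alignment and for relabelings", {
  D <- rand_dissim(6, seed = 3)
  expect_lt(gw_cost(D, D, diag(6) / 6), 1e-12)

  # cyclic relabeling of a 3-item structure with off-diagonals 1, 2, 3:
  # coupling item i of D to the position holding i after relabeling
  m <- matrix(0, 3, 3)
  m[upper.tri(m)] <- c(1, 2, 3)
  m <- m + t(m)
  perm <- c(2, 3, 1)
  mp <- m[perm, perm]
  P <- matrix(0, 3, 3)
  P[cbind(perm, seq_len(3))] <- 1 / 3
  expect_equal(gw_cost(dissim_matrix(m), dissim_matrix(mp), P), 0)
  expect_equal(brute_gw_cost(m, mp, P), 0)
})

test_that("gw_cost rejects mismatched dimensions", {
  expect_error(gw_cost(rand_dissim(4, 1), rand_dissim(5, 2), diag(4) / 4),
               "dimensions")
})

test_that("random couplings have uniform marginals, are seeded and distinct", {
  g <- random_coupling(3, 3, 11)
  expect_lt(max(abs(rowSums(g) - 1 / 3)), 1e-8)
  expect_lt(max(abs(colSums(g) - 1 / 3)), 1e-8)
  expect_true(all(unclass(g) > 0))

  expect_identical(unclass(random_coupling(5, 7, 42)),
                   unclass(random_coupling(5, 7, 42)))
  delta <- abs(unclass(random_coupling(5, 7, 1)) -
                 unclass(random_coupling(5, 7, 2)))
  expect_gt(max(delta), 1e-6)

  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(random_coupling(4, 4, 9)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("entropic solver recovers self-alignment and respects limits", {
  D <- normalize_dissim(rand_dissim(8, seed = 5))
  near_id <- 0.9 * diag(8) / 8 + 0.1 / 64
  rec <- entropic_gw(D, D, 1e-3, init = transport_plan(near_id))
  mr <- matching_rate(rec$plan, dissim_labels(D), dissim_labels(D))
  expect_equal(mr$matching_rate, 100)

  # entropy-dominated limit: plan collapses to the uniform outer product
  rec_big <- entropic_gw(D, D, 50, init = random_coupling(8, 8, 3))
  expect_lt(max(abs(unclass(rec_big$plan) - 1 / 64)), 1e-3)

  expect_error(entropic_gw(D, D, 0), "positive")
  expect_error(entropic_gw(D, D, -1), "positive")
})

test_that("sweep beats the exhaustive permutation oracle on small problems", {
  for (seed in c(101, 202)) {
    n <- 5
    D <- normalize_dissim(rand_dissim(n, seed = seed))
    pr <- make_pair(D, 0, seed = seed + 1)
    Dp <- normalize_dissim(pr$target)
    sw <- gw_sweep(D, Dp, n_trials = 10, seed = seed, eps_min = 1e-4,
                   eps_max = 1e-1)
    opt <- select_optimum(sw)
    expect_lte(opt$gwd_plain, perm_min_gw(D, Dp) + 1e-6)
  }
})

test_that("sweep handles self-alignment, degenerate sizes and bookkeeping", {
  D <- normalize_dissim(rand_dissim(10, seed = 8))
  sw <- gw_sweep(D, D, n_trials = 20, seed = 2,
                 labels1 = dissim_labels(D), labels2 = dissim_labels(D))
  opt <- select_optimum(sw)
  expect_lt(opt$gwd_plain, 1e-6)
  expect_equal(matching_rate(opt$plan, dissim_labels(D),
                             dissim_labels(D))$matching_rate, 100)

  one <- gw_sweep(D, D, n_trials = 1, seed = 3)
  expect_length(one$records, 1)
  expect_identical(one$optimal_index, 1L)
  expect_identical(select_optimum(one), one$records[[1]])

  tb <- sweep_table(sw)
  expect_named(tb, c("epsilon", "seed", "gwd_entropic", "gwd_plain",
                     "matching_rate", "n_iterations", "converged"))
  expect_equal(nrow(tb), 20)
  expect_true(all(tb$gwd_plain >= 0))
  expect_true(all(tb$epsilon >= 1e-4 * (1 - 1e-12) &
                    tb$epsilon <= 1e-1 * (1 + 1e-12)))
})

test_that("every plan returned by a sweep satisfies the marginal constraints", {
  D <- normalize_dissim(rand_dissim(12, seed = 14))
  pr <- make_pair(D, 0.02, seed = 15)
  sw <- gw_sweep(D, normalize_dissim(pr$target), n_trials = 15, seed = 5)
  for (rec in sw$records) {
    G <- unclass(rec$plan)
    expect_lt(max(abs(rowSums(G) - 1 / 12)), 1e-6)
    expect_lt(max(abs(colSums(G) - 1 / 12)), 1e-6)
    expect_gte(min(G), 0)
    expect_lt(abs(sum(G) - 1), 1e-9)
  }
})

test_that("optimum selection minimizes plain GWD with documented tie-breaks", {
  mk <- function(eps, gwd, conv = TRUE) {
    list(epsilon = eps, seed = 1L, plan = NULL, gwd_plain = gwd,
         gwd_entropic = gwd, n_iterations = 1L, converged = conv)
  }
  fake <- structure(list(records = list(mk(1e-3, 0.3), mk(1e-2, 0.1),
                                        mk(1e-1, 0.2)),
                         optimal_index = 2L, eps_grid = c(1e-3, 1e-2, 1e-1),
                         seed = 1), class = "gw_sweep")
  expect_equal(select_optimum(fake)$gwd_plain, 0.1)

  # tie on gwd_plain resolves toward the smaller epsilon
  recs <- list(mk(1e-2, 0.2), mk(1e-3, 0.2), mk(1e-1, 0.5))
  conv <- c(TRUE, TRUE, TRUE)
  gwd <- vapply(recs, `[[`, numeric(1), "gwd_plain")
  eps <- vapply(recs, `[[`, numeric(1), "epsilon")
  best <- order(gwd, eps, seq_along(recs))[1]
  expect_equal(best, 2)
})

test_that("matching degrades monotonically as synthetic noise grows", {
  levels <- c(0, 0.1, 0.3, 1.0)
  n_rep <- 20
  rates <- matrix(NA_real_, n_rep, length(levels))
  for (r in seq_len(n_rep)) {
    base <- normalize_dissim(sample_structure(10, seed = 500 + r)$dissim)
    rel <- mean(base[upper.tri(base)])
    for (li in seq_along(levels)) {
      pr <- make_pair(base, levels[li] * rel, seed = 600 + 10 * r + li)
      sw <- gw_sweep(base, normalize_dissim(pr$target), n_trials = 8,
                     seed = 700 + r)
      opt <- select_optimum(sw)
      rates[r, li] <- matching_rate(opt$plan, dissim_labels(base),
                                    dissim_labels(pr$target))$matching_rate
    }
  }
  means <- colMeans(rates)
  inversions <- sum(diff(means) > 0)
  expect_lte(inversions, 1)
  expect_gt(means[1], means[length(levels)])
})
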