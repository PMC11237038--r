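test_that("constructor enforces the dissimilarity-matrix invariants", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  d <- dissim_matrix(m, labels = c("a", "b"))
  expect_s3_class(d, "dissim")
  expect_identical(dissim_labels(d), c("a", "b"))
  expect_false(attr(d, "normalized"))

  expect_error(dissim_matrix(matrix(1:6, 2, 3)), "square")
  expect_error(dissim_matrix(m, labels = c("a", "a")), "duplicate")
  bad <- m; bad[1, 2] <- 1.5
  expect_error(dissim_matrix(bad), "asymmetric")
  expect_error(dissim_matrix(matrix(c(0, -1, -1, 0), 2, 2)), "nonnegative")
  diagbad <- m; diag(diagbad) <- 2
  expect_error(dissim_matrix(diagbad), "diagonal")
  expect_error(dissim_matrix(m * 3, normalized = TRUE), "normalized")
})

test_that("rating aggregation pools unordered pairs into means", {
  tb <- data.frame(item_a = c("a", "b"), item_b = c("b", "a"),
                   rating = c(2, 4), rater = c("r1", "r2"))
  d <- dissim_from_ratings(tb)
  expect_equal(d["a", "b"], 3)
  expect_equal(d["b", "a"], 3)
  expect_equal(diag(unclass(d)), c(a = 0, b = 0))

  zero <- data.frame(item_a = c("a", "a", "b"), item_b = c("b", "c", "c"),
                     rating = 0)
  expect_true(all(unclass(dissim_from_ratings(zero)) == 0))

  expect_error(dissim_from_ratings(
    data.frame(item_a = c("a", "a"), item_b = c("b", "c"), rating = 1)),
    "no rating for pair \\{b, c\\}")
  expect_error(dissim_from_ratings(
    data.frame(item_a = "a", item_b = "b", rating = 9)), "\\[0, 7\\]")
})

test_that("rating aggregation matches a brute-force pairwise mean on a simulated panel", {
  base <- normalize_dissim(rand_dissim(4, seed = 21))
  tb <- simulate_rater_panel(base, n_raters = 3, rater_noise_sd = 0.8,
                             seed = 5)
  d <- dissim_from_ratings(tb, labels = dissim_labels(base))
  # independent mean over the generated rows
  for (i in 1:3) for (j in (i + 1):4) {
    la <- dissim_labels(base)[i]; lb <- dissim_labels(base)[j]
    rows <- (tb$item_a == la & tb$item_b == lb) |
      (tb$item_a == lb & tb$item_b == la)
    expect_equal(d[la, lb], mean(tb$rating[rows]))
  }
})

test_that("rating aggregation is invariant to row order and pair orientation", {
  base <- normalize_dissim(rand_dissim(5, seed = 31))
  tb <- simulate_rater_panel(base, n_raters = 4, seed = 9)
  d1 <- dissim_from_ratings(tb, labels = dissim_labels(base))
  shuffled <- tb[rev(seq_len(nrow(tb))), ]
  flipped <- shuffled
  flip <- seq_len(nrow(flipped)) %% 2 == 0
  tmp <- flipped$item_a[flip]
  flipped$item_a[flip] <- flipped$item_b[flip]
  flipped$item_b[flip] <- tmp
  d2 <- dissim_from_ratings(flipped, labels = dissim_labels(base))
  expect_equal(unclass(d1), unclass(d2))
})

test_that("normalization scales by the maximum, is idempotent and rank-preserving", {
  m <- matrix(0, 3, 3)
  m[upper.tri(m)] <- c(0, 2, 5)
  m <- m + t(m)
  d <- normalize_dissim(dissim_matrix(m))
  expect_true(attr(d, "normalized"))
  expect_equal(sort(unique(as.vector(unclass(d)))), c(0, 0.4, 1))

  d7 <- dissim_matrix(matrix(c(0, 7, 7, 0), 2, 2))
  expect_equal(max(normalize_dissim(d7)), 1)

  expect_equal(unclass(normalize_dissim(d)), unclass(d))  # idempotent

  r <- rand_dissim(8, seed = 4)
  rn <- normalize_dissim(r)
  expect_equal(cor(r[upper.tri(r)], rn[upper.tri(rn)], method = "spearman"),
               1)

  z <- dissim_matrix(matrix(0, 3, 3))
  zn <- normalize_dissim(z)
  expect_true(all(unclass(zn) == 0) && attr(zn, "normalized"))
})

test_that("matrix CSV round-trips to machine precision and rejects bad files", {
  d <- rand_dissim(5, seed = 77)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dissim_csv(d, path)
  d2 <- read_dissim_csv(path)
  expect_identical(dissim_labels(d2), dissim_labels(d))
  expect_lt(max(abs(unclass(d2) - unclass(d))), 1e-12)

  asym <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "0,0.5", "1.0,0"), asym)
  expect_error(read_dissim_csv(asym), "asymmetric")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,a", "0,1", "1,0"), dup)
  expect_error(read_dissim_csv(dup), "duplicate")

  nonsq <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "0,1", "1,0", "2,2"), nonsq)
  expect_error(read_dissim_csv(nonsq), "non-square")

  nonnum <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "0,x", "x,0"), nonnum)
  expect_error(read_dissim_csv(nonnum), "non-numeric")
})
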