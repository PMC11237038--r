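#' Sample a Euclidean dissimilarity structure
#'
#' Draws `n` i.i.d. standard-normal points in `dim`-space and returns the
#' point cloud with its pairwise Euclidean dissimilarity matrix. Euclidean
#' construction guarantees the triangle inequality. Deterministic per seed.
#'
#' @param n Number of items (>= 3).
#' @param dim Ambient dimensionality (default 3).
#' @param seed Integer seed.
#' @param labels Optional item labels.
#' @return List with `points` (`n x dim`) and `dissim` (a `dissim` object).
#' @export
sample_structure <- function(n, dim = 3, seed = 1, labels = NULL) {
  stopifnot(n >= 3, dim >= 1)
  pts <- with_local_seed(seed, matrix(stats::rnorm(n * dim), n, dim))
  if (is.null(labels)) labels <- paste0("item", seq_len(n))
  list(points = pts,
       dissim = dissim_matrix(as.matrix(stats::dist(pts)), labels = labels))
}

# symmetric additive Gaussian perturbation of the off-diagonals,
# clipped at zero
perturb_offdiag <- function(m, noise_sd) {
  if (noise_sd <= 0) return(m)
  n <- nrow(m)
  up <- upper.tri(m)
  noise <- matrix(0, n, n)
  noise[up] <- stats::rnorm(sum(up), 0, noise_sd)
  m <- m + noise + t(noise)
  m[m < 0] <- 0
  diag(m) <- 0
  m
}

new_synthetic_pair <- function(source, target, perm, params) {
  stopifnot(!anyDuplicated(perm), length(perm) == nrow(target))
  structure(list(source = source, target = target,
                 true_permutation = perm, params = params),
            class = "synthetic_pair")
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf("Synthetic structure pair: %d items (%s)\n",
              nrow(x$source),
              paste(names(x$params), unlist(lapply(x$params, function(p)
                paste(format(p), collapse = "/"))),
                sep = "=", collapse = ", ")))
  invisible(x)
}

#' Noisy, relabeled copy of a dissimilarity structure
#'
#' Builds a ground-truthed alignment problem: the target is the source with
#' independent Gaussian noise added to the (upper-triangle) off-diagonals,
#' mirrored, clipped at zero, and — when `permute = TRUE` — re-indexed by a
#' random permutation. With `noise_sd = 0` the target equals the source
#' exactly under the recorded permutation.
#'
#' @param base A `dissim` object.
#' @param noise_sd Standard deviation of the additive noise (same units as
#'   the entries of `base`).
#' @param seed Integer seed.
#' @param permute Re-index the target items randomly (default `TRUE`).
#' @return A `synthetic_pair`: `source`, `target`, `true_permutation` (the
#'   target position of each source item), `params`.
#' @export
make_pair <- function(base, noise_sd = 0, seed = 1, permute = TRUE) {
  stopifnot(is_dissim(base), noise_sd >= 0)
  n <- nrow(base)
  out <- with_local_seed(seed, {
    vals <- perturb_offdiag(as_plain_matrix(base), noise_sd)
    perm <- if (permute) sample.int(n) else seq_len(n)
    list(vals = vals, perm = perm)
  })
  tv <- matrix(0, n, n)
  tv[out$perm, out$perm] <- out$vals
  tl <- character(n)
  tl[out$perm] <- dissim_labels(base)
  target <- dissim_matrix(tv, labels = tl,
                          normalized = isTRUE(attr(base, "normalized")) &&
                            noise_sd == 0)
  new_synthetic_pair(base, target, out$perm,
                     list(n = n, noise_sd = noise_sd, seed = seed,
                          permute = permute))
}

#' Category-structured pair dissociating correlation from matching
#'
#' Generates two dissimilarity structures over the same items, each item
#' carrying a coarse category identity: category centers are placed randomly
#' in `dim`-space and rescaled so the mean between-center distance is
#' `between_sep`; items jitter around their center with the offsets rescaled
#' so the mean within-category pairwise distance is `within_scale`. With
#' `resample_fine = TRUE` the target's within-category offsets are redrawn
#' independently while the category geometry is kept, which yields pairs
#' whose entries correlate strongly (the coarse blocks agree) even though no
#' fine item-level correspondence exists — so supervised correlation is high
#' while unsupervised matching sits at chance. With `resample_fine = FALSE`
#' the target is an exact (optionally noisy, permuted) copy.
#'
#' @param n_categories Number of coarse categories (>= 2).
#' @param items_per_category Items per category (>= 2).
#' @param between_sep Mean distance between category centers.
#' @param within_scale Mean within-category pairwise distance
#'   (`<< between_sep` for clear category structure).
#' @param resample_fine Redraw the target's fine structure independently.
#' @param noise_sd Additional Gaussian noise on the target off-diagonals.
#' @param seed Integer seed.
#' @param dim Ambient dimensionality (default 3).
#' @param permute Randomly re-index the target items (default `TRUE`).
#' @return A `synthetic_pair`; `params$categories` records each item's
#'   category.
#' @export
make_category_pair <- function(n_categories = 3, items_per_category = 31,
                               between_sep = 1, within_scale = 0.25,
                               resample_fine = FALSE, noise_sd = 0,
                               seed = 1, dim = 3, permute = TRUE) {
  stopifnot(n_categories >= 2, items_per_category >= 2)
  k <- n_categories
  ipc <- items_per_category
  n <- k * ipc
  cats <- rep(seq_len(k), each = ipc)
  labels <- paste0("c", cats, "_", rep(seq_len(ipc), k))

  scaled_points <- function(centers, cats, within_scale) {
    off <- matrix(stats::rnorm(length(cats) * ncol(centers)),
                  ncol = ncol(centers))
    pts <- centers[cats, , drop = FALSE] + off
    within <- unlist(lapply(unique(cats), function(cc) {
      stats::dist(pts[cats == cc, , drop = FALSE] -
                    centers[rep(cc, sum(cats == cc)), , drop = FALSE])
    }))
    centers[cats, , drop = FALSE] + off * (within_scale / mean(within))
  }

  gen <- with_local_seed(seed, {
    centers <- matrix(stats::rnorm(k * dim), k, dim)
    centers <- centers * (between_sep / mean(stats::dist(centers)))
    src_pts <- scaled_points(centers, cats, within_scale)
    tgt_pts <- if (resample_fine) scaled_points(centers, cats, within_scale)
               else src_pts
    tgt_vals <- perturb_offdiag(as.matrix(stats::dist(tgt_pts)), noise_sd)
    perm <- if (permute) sample.int(n) else seq_len(n)
    list(src = as.matrix(stats::dist(src_pts)), tgt = tgt_vals, perm = perm)
  })
  source <- dissim_matrix(gen$src, labels = labels)
  tv <- matrix(0, n, n)
  tv[gen$perm, gen$perm] <- gen$tgt
  tl <- character(n)
  tl[gen$perm] <- labels
  target <- dissim_matrix(tv, labels = tl)
  new_synthetic_pair(source, target, gen$perm,
                     list(n = n, n_categories = k,
                          items_per_category = ipc,
                          between_sep = between_sep,
                          within_scale = within_scale,
                          resample_fine = resample_fine,
                          noise_sd = noise_sd, seed = seed, dim = dim,
                          categories = cats))
}

#' Simulate a panel of raters producing discrete similarity judgments
#'
#' Emulates group-averaged human similarity-judgment data: each rater's
#' rating of pair `(i, j)` is the base dissimilarity scaled to the rating
#' scale, plus Gaussian rater noise, clipped to `[0, scale_max]` and rounded
#' to the nearest integer (a discrete 0-to-`scale_max` response). The output
#' is a long-format rating table from which [dissim_from_ratings()] rebuilds
#' a noisy group-average matrix.
#'
#' @param base A normalized `dissim` object (entries in `[0, 1]`).
#' @param n_raters Number of raters (>= 1).
#' @param scale_max Top of the rating scale (default 7).
#' @param rater_noise_sd Rater noise standard deviation, in rating units.
#' @param seed Integer seed.
#' @return Data frame with columns `item_a`, `item_b`, `rating`, `rater`
#'   (one row per unordered pair per rater).
#' @export
simulate_rater_panel <- function(base, n_raters, scale_max = 7,
                                 rater_noise_sd = 0.5, seed = 1) {
  stopifnot(is_dissim(base), n_raters >= 1)
  if (!isTRUE(attr(base, "normalized"))) {
    stop("`base` must be normalized (entries in [0, 1])", call. = FALSE)
  }
  labels <- dissim_labels(base)
  up <- which(upper.tri(base), arr.ind = TRUE)
  vals <- as_plain_matrix(base)[up]
  npair <- nrow(up)
  ratings <- with_local_seed(seed, {
    noise <- stats::rnorm(npair * n_raters, 0, rater_noise_sd)
    round(pmin(pmax(rep(scale_max * vals, n_raters) + noise, 0), scale_max))
  })
  data.frame(
    item_a = rep(labels[up[, 1]], n_raters),
    item_b = rep(labels[up[, 2]], n_raters),
    rating = ratings,
    rater = rep(paste0("rater", seq_len(n_raters)), each = npair),
    stringsAsFactors = FALSE
  )
}

#' Simulate trial-averaged continuous ratings
#'
#' Emulates a rating agent queried repeatedly with the same prompt and a
#' nonzero sampling temperature (e.g. a language model asked for a real-
#' valued dissimilarity rating): each trial reads out the base structure on
#' the 0-to-`scale_max` continuous rating scale with symmetric Gaussian
#' trial noise, clipped to range, and the trials are averaged.
#'
#' @param base A `dissim` object (typically normalized).
#' @param n_trials Number of trials to average (default 5).
#' @param trial_noise_sd Trial noise standard deviation, in rating units.
#' @param scale_max Top of the rating scale (default 7).
#' @param seed Integer seed.
#' @return A `dissim` object on the rating scale (not normalized).
#' @export
simulate_llm_trials <- function(base, n_trials = 5, trial_noise_sd = 0.5,
                                scale_max = 7, seed = 1) {
  stopifnot(is_dissim(base), n_trials >= 1)
  m0 <- pmin(scale_max * as_plain_matrix(base), scale_max)
  acc <- with_local_seed(seed, {
    tot <- matrix(0, nrow(m0), ncol(m0))
    for (t in seq_len(n_trials)) {
      mt <- perturb_offdiag(m0, trial_noise_sd)
      tot <- tot + pmin(mt, scale_max)
    }
    tot / n_trials
  })
  dissim_matrix(acc, labels = dissim_labels(base))
}
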