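#' Metric MDS embedding of a dissimilarity matrix
#'
#' Stress-minimizing metric multidimensional scaling by the SMACOF
#' majorization (Guttman transform) algorithm: starting from the classical
#' (Torgerson) solution and `n_restarts - 1` seeded random configurations,
#' each start is iterated to a stationary configuration and the lowest-stress
#' one is kept. Deterministic given `seed`.
#'
#' @param D A `dissim` object.
#' @param dim Embedding dimensionality (default 3); must be `< n`.
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Number of starts (first is classical MDS; default 8).
#' @param max_iter,tol Majorization iteration cap and relative raw-stress
#'   convergence threshold.
#' @return An `embedding` object: list with `labels`, `coords` (`dim x n`,
#'   items as columns), `dim`, `stress` (normalized stress-1), `raw_stress`.
#' @export
mds_embed <- function(D, dim = 3, seed = 1, n_restarts = 8, max_iter = 500,
                      tol = 1e-12) {
  stopifnot(is_dissim(D), dim >= 1)
  n <- nrow(D)
  if (dim >= n) stop("dim must be smaller than the number of items",
                     call. = FALSE)
  delta <- as_plain_matrix(D)
  inits <- with_local_seed(seed, {
    c(list(cmdscale_init(delta, dim)),
      lapply(seq_len(max(0, n_restarts - 1)), function(i) {
        matrix(stats::rnorm(n * dim), n, dim)
      }))
  })
  best <- NULL
  for (X0 in inits) {
    fit <- smacof_fit(delta, X0, max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$raw_stress < best$raw_stress) best <- fit
  }
  structure(list(labels = dissim_labels(D),
                 coords = t(best$X),
                 dim = dim,
                 stress = sqrt(best$raw_stress / sum(delta^2) * 2),
                 raw_stress = best$raw_stress),
            class = "embedding")
}

cmdscale_init <- function(delta, dim) {
  cs <- stats::cmdscale(delta, k = dim)
  if (ncol(cs) < dim) {
    cs <- cbind(cs, matrix(0, nrow(cs), dim - ncol(cs)))
  }
  cs
}

# one SMACOF run: minimize raw stress sum_{i<j} (d_ij(X) - delta_ij)^2
smacof_fit <- function(delta, X, max_iter, tol) {
  n <- nrow(delta)
  d <- as.matrix(stats::dist(X))
  stress <- sum((d[upper.tri(d)] - delta[upper.tri(delta)])^2)
  for (it in seq_len(max_iter)) {
    ratio <- ifelse(d > 0, delta / d, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    d <- as.matrix(stats::dist(X))
    stress_new <- sum((d[upper.tri(d)] - delta[upper.tri(delta)])^2)
    if (stress - stress_new < tol * max(stress, .Machine$double.eps)) {
      stress <- stress_new
      break
    }
    stress <- stress_new
  }
  list(X = X, raw_stress = stress)
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("%d-dimensional embedding of %d items (stress-1 = %.4g)\n",
              x$dim, length(x$labels), x$stress))
  invisible(x)
}

#' Pairwise distances of an embedding
#'
#' @param E An `embedding` object.
#' @return A symmetric matrix of Euclidean distances between item columns.
#' @export
embedding_distances <- function(E) {
  as.matrix(stats::dist(t(E$coords)))
}

#' Plan-weighted Procrustes rotation of one embedding onto another
#'
#' Finds the orthogonal matrix `Q` minimizing
#' \deqn{\|X - Q\,\tilde{Y}\|_F^2,} where `X` (`d x n`) holds the source
#' coordinates and \eqn{\tilde{Y}} is the barycentric projection of the
#' target coordinates through the transportation plan: column `i` of
#' \eqn{\tilde{Y}} is \eqn{\sum_k \Gamma_{ik} Y_{\cdot k} / p_i} (the
#' plan-weighted average of target points corresponding to source item `i`;
#' the division by the source marginal undoes the plan's mass scaling so
#' aligned coordinates live on the scale of the originals). The solution is
#' `Q = U V'` from the singular value decomposition
#' \eqn{X \tilde{Y}^\top = U \Sigma V^\top}. Reflections are allowed: `Q` is
#' constrained to be orthogonal, not special-orthogonal.
#'
#' @param X Source `embedding` (`n` items).
#' @param Y Target `embedding` (`m` items), same `dim` as `X`.
#' @param plan An `n x m` `transport_plan` linking the two item sets.
#' @return A `rotation_result`: list with `Q` (`d x d` orthogonal), `aligned`
#'   (`d x m`: all target coordinates rotated by `Q`), `projected` (`d x n`:
#'   \eqn{Q\tilde{Y}}, the rotated plan-projection of the target onto the
#'   source items), and `residual`
#'   (\eqn{\|X - Q\tilde{Y}\|_F}).
#' @export
procrustes_align <- function(X, Y, plan) {
  stopifnot(inherits(X, "embedding"), inherits(Y, "embedding"))
  if (X$dim != Y$dim) stop("embeddings have different dimensionality",
                           call. = FALSE)
  G <- unclass(plan)
  n <- length(X$labels)
  m <- length(Y$labels)
  if (nrow(G) != n || ncol(G) != m) {
    stop("plan dimensions do not match the embeddings", call. = FALSE)
  }
  p <- rowSums(G)
  Yt <- Y$coords %*% t(G)            # d x n, columns scaled by p
  Yt <- sweep(Yt, 2, p, `/`)         # barycentric projection
  M <- X$coords %*% t(Yt)
  sv <- svd(M)
  Q <- sv$u %*% t(sv$v)
  projected <- Q %*% Yt
  structure(list(Q = Q,
                 aligned = Q %*% Y$coords,
                 projected = projected,
                 residual = sqrt(sum((X$coords - projected)^2))),
            class = "rotation_result")
}

#' @export
print.rotation_result <- function(x, ...) {
  cat(sprintf("Procrustes rotation: %d x %d, det(Q) = %+.0f, residual = %.4g\n",
              nrow(x$Q), ncol(x$Q), det(x$Q), x$residual))
  invisible(x)
}
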