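# Independent oracles used across the test files. Everything here is written
# against the mathematical definitions directly (explicit loops, exhaustive
# enumeration, a conditional-gradient solver with exact assignment steps) and
# never calls the package's own computational path.

# explicit four-index GW objective
brute_gw_cost <- function(D, Dp, G) {
  D <- unclass(D); Dp <- unclass(Dp); G <- unclass(G)
  n <- nrow(D); m <- nrow(Dp)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    for (k in seq_len(m)) for (l in seq_len(m)) {
      total <- total + (D[i, j] - Dp[k, l])^2 * G[i, k] * G[j, l]
    }
  }
  total
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos - 1)
    }
  }
  out
}

# exhaustive minimum of the GW objective over permutation couplings
perm_min_gw <- function(D, Dp) {
  D <- unclass(D); Dp <- unclass(Dp)
  n <- nrow(D)
  best <- Inf
  for (perm in all_perms(n)) {
    # coupling that maps i -> perm[i]: cost sum_ij (D_ij - Dp[perm_i, perm_j])^2 / n^2
    val <- sum((D - Dp[perm, perm])^2) / n^2
    if (val < best) best <- val
  }
  best
}

# Independent entropic-free GW solver: Frank-Wolfe (conditional gradient) on
# the coupling polytope; the linear subproblem for uniform marginals is an
# assignment problem solved exactly by clue::solve_LSAP. Exact line search
# for the quadratic objective.
fw_gw <- function(D, Dp, G0, max_iter = 300) {
  D <- unclass(D); Dp <- unclass(Dp)
  n <- nrow(D); m <- nrow(Dp)
  stopifnot(n == m)  # assignment step assumes square uniform problems
  p <- rep(1 / n, n); q <- rep(1 / m, m)
  cC <- outer(as.vector(D^2 %*% p), rep(1, m)) +
    outer(rep(1, n), as.vector(Dp^2 %*% q))
  obj <- function(G) {
    sum(cC * G) - 2 * sum(G * (D %*% G %*% Dp))
  }
  G <- G0
  for (it in seq_len(max_iter)) {
    grad <- 2 * (cC - 2 * (D %*% G %*% Dp))
    shift <- min(grad)
    asg <- clue::solve_LSAP(grad - shift + 1e-9)
    S <- matrix(0, n, m)
    S[cbind(seq_len(n), as.integer(asg))] <- 1 / n
    Dlt <- S - G
    b <- sum(grad * Dlt)
    a <- -2 * sum(Dlt * (D %*% Dlt %*% Dp))
    if (b > -1e-15) break
    t_step <- if (a > 0) min(1, max(0, -b / (2 * a))) else 1
    if (t_step <= 0) break
    G <- G + t_step * Dlt
  }
  list(plan = G, gwd = obj(G))
}

# random orthogonal matrix via QR with sign fix
random_orthogonal <- function(d) {
  qr_ <- qr(matrix(stats::rnorm(d * d), d, d))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), d)
}

# small random symmetric dissimilarity matrix with distinct entries
rand_dissim <- function(n, seed, labels = paste0("x", seq_len(n))) {
  sample_structure(n, dim = 3, seed = seed, labels = labels)$dissim
}

# seeded permutation without touching the ambient RNG stream
with_seed_perm <- function(seed, n) {
  withr::with_seed(seed, sample.int(n))
}

# strict upper-triangle entries of a (possibly classed) square matrix
upper_entries_of <- function(D) {
  m <- unclass(D)
  m[upper.tri(m)]
}
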