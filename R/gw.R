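#' Transportation plan (coupling matrix)
#'
#' Validates an `n x m` nonnegative coupling whose rows sum to the source
#' marginal `p` and whose columns sum to the target marginal `q`. Entry
#' `(i, k)` is read as the probability that source item `i` corresponds to
#' target item `k`.
#'
#' @param values Numeric `n x m` nonnegative matrix.
#' @param p Source marginal (length `n`); default uniform `1/n`.
#' @param q Target marginal (length `m`); default uniform `1/m`.
#' @param tol Tolerance for the marginal-sum checks (total mass is checked at
#'   `1e-9`).
#' @return An object of class `transport_plan` with attributes `p` and `q`.
#' @export
transport_plan <- function(values, p = NULL, q = NULL, tol = 1e-6) {
  stopifnot(is.matrix(values), is.numeric(values))
  n <- nrow(values)
  m <- ncol(values)
  if (is.null(p)) p <- rep(1 / n, n)
  if (is.null(q)) q <- rep(1 / m, m)
  if (length(p) != n || length(q) != m) {
    stop("marginal lengths do not match plan dimensions", call. = FALSE)
  }
  if (min(values) < 0) stop("coupling entries must be nonnegative",
                            call. = FALSE)
  if (abs(sum(values) - 1) > 1e-9) {
    stop("coupling total mass must be 1 (got ", format(sum(values)), ")",
         call. = FALSE)
  }
  if (max(abs(rowSums(values) - p)) > tol) {
    stop("row sums violate the source marginal beyond tolerance",
         call. = FALSE)
  }
  if (max(abs(colSums(values) - q)) > tol) {
    stop("column sums violate the target marginal beyond tolerance",
         call. = FALSE)
  }
  structure(values, p = p, q = q, class = c("transport_plan", "matrix"))
}

#' @export
print.transport_plan <- function(x, ...) {
  cat(sprintf("Transportation plan: %d x %d, mass %.6f\n", nrow(x), ncol(x),
              sum(x)))
  invisible(x)
}

#' Random coupling with uniform marginals
#'
#' Samples i.i.d. strictly positive entries and projects them onto the
#' polytope of couplings with uniform marginals `(1/n, 1/m)` by Sinkhorn
#' (iterative proportional fitting). Deterministic given `seed`; the caller's
#' RNG state is left untouched.
#'
#' @param n,m Plan dimensions.
#' @param seed Integer seed.
#' @return A `transport_plan`.
#' @export
random_coupling <- function(n, m, seed) {
  stopifnot(n >= 1, m >= 1)
  g <- with_local_seed(seed, matrix(stats::runif(n * m, 0.1, 1), n, m))
  p <- rep(1 / n, n)
  q <- rep(1 / m, m)
  for (it in seq_len(1000)) {
    g <- g * (p / rowSums(g))
    g <- sweep(g, 2, q / colSums(g), `*`)
    if (max(abs(rowSums(g) - p)) < 1e-10) break
  }
  g <- g * (p / rowSums(g))
  transport_plan(g, p, q)
}

# evaluate an expression under a temporary RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# splittable per-trial seed stream: deterministic, collision-poor, < 2^31
derive_seed <- function(master, trial) {
  as.integer(((as.numeric(master) %% 2147483647) * 48271 +
                as.numeric(trial) * 104729) %% 2147483629 + 1)
}

#' Gromov-Wasserstein transport cost of a plan
#'
#' Evaluates the quadratic GW objective
#' \deqn{\sum_{i,j,k,l} (D_{ij} - D'_{kl})^2 \Gamma_{ik} \Gamma_{jl}}
#' for a fixed coupling, via the factored tensor contraction
#' \eqn{\sum_{ij} D_{ij}^2 p_i p_j + \sum_{kl} D'^2_{kl} q_k q_l -
#' 2\,\mathrm{tr}(\Gamma^\top D \Gamma D')} (never the explicit four-index
#' loop), where `p`, `q` are the plan's marginals.
#'
#' @param D,Dp Source and target dissimilarity matrices (`dissim` or plain
#'   numeric matrices), `n x n` and `m x m`.
#' @param plan An `n x m` `transport_plan` (or plain coupling matrix).
#' @return Nonnegative scalar.
#' @export
gw_cost <- function(D, Dp, plan) {
  D <- as_plain_matrix(D)
  Dp <- as_plain_matrix(Dp)
  G <- unclass(plan)
  if (nrow(G) != nrow(D) || ncol(G) != nrow(Dp)) {
    stop("plan dimensions (", nrow(G), " x ", ncol(G),
         ") do not match the structures (", nrow(D), ", ", nrow(Dp), ")",
         call. = FALSE)
  }
  p <- rowSums(G)
  q <- colSums(G)
  const <- sum((D^2 %*% p) * p) + sum((Dp^2 %*% q) * q)
  val <- const - 2 * sum(G * (D %*% G %*% Dp))
  max(val, 0)
}

#' Entropic Gromov-Wasserstein local optimum
#'
#' Minimizes the entropy-regularized GW objective
#' \deqn{\sum_{i,j,k,l}(D_{ij}-D'_{kl})^2\Gamma_{ik}\Gamma_{jl}
#'   - \epsilon H(\Gamma)}
#' with \eqn{H(\Gamma) = -\sum_{ik}\Gamma_{ik}(\log\Gamma_{ik}-1)}, by
#' projected mirror descent: each outer step forms the partial-gradient cost
#' tensor of the quadratic term and solves the resulting entropic linear OT
#' subproblem by log-domain Sinkhorn scaling at temperature `epsilon`
#' (warm-started across outer steps). The problem is non-convex; the returned
#' plan is a local optimum that depends on `init`.
#'
#' @param D,Dp Dissimilarity matrices (`n x n`, `m x m`); uniform marginals
#'   are used.
#' @param epsilon Positive entropy-regularization weight.
#' @param init Initial `transport_plan` (e.g. [random_coupling()]); default is
#'   the uniform outer product.
#' @param max_outer Outer-iteration cap.
#' @param tol Convergence threshold on the change of the plain (unregularized)
#'   GW objective between successive outer iterations.
#' @param sinkhorn_tol,sinkhorn_max Inner Sinkhorn marginal tolerance and
#'   iteration cap.
#' @param anneal Solve the first subproblem through a short temperature
#'   ladder down to `epsilon` (default `TRUE`); disable to continue a
#'   warm-started descent without the smoothed restart.
#' @return A `gw_record`: list with `epsilon`, `seed` (`NA` here; filled by
#'   [gw_sweep()]), `plan`, `gwd_plain` (unregularized objective of the
#'   returned plan), `gwd_entropic` (regularized objective), `n_iterations`,
#'   `converged`.
#' @export
entropic_gw <- function(D, Dp, epsilon, init = NULL, max_outer = 1000,
                        tol = 1e-9, sinkhorn_tol = 1e-8,
                        sinkhorn_max = 2000, anneal = TRUE) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    stop("epsilon must be a positive scalar", call. = FALSE)
  }
  D <- as_plain_matrix(D)
  Dp <- as_plain_matrix(Dp)
  n <- nrow(D)
  m <- nrow(Dp)
  p <- rep(1 / n, n)
  q <- rep(1 / m, m)
  if (is.null(init)) {
    G0 <- outer(p, q)
  } else {
    G0 <- unclass(init)
    if (nrow(G0) != n || ncol(G0) != m) {
      stop("init plan dimensions do not match the structures", call. = FALSE)
    }
  }
  out <- .entropic_gw_core(D, Dp, epsilon, G0, as.integer(max_outer), tol,
                           sinkhorn_tol, as.integer(sinkhorn_max),
                           isTRUE(anneal))
  if (isTRUE(out$overflow)) {
    stop("Sinkhorn overflow at epsilon = ", format(epsilon),
         "; epsilon is too small for the cost scale", call. = FALSE)
  }
  G <- out$plan
  ent <- -sum(G[G > 0] * (log(G[G > 0]) - 1))
  rec <- list(
    epsilon = epsilon,
    seed = NA_integer_,
    plan = transport_plan(G, p, q),
    gwd_plain = out$gwd_plain,
    gwd_entropic = out$gwd_plain - epsilon * ent,
    n_iterations = out$n_iterations,
    converged = out$converged
  )
  class(rec) <- "gw_record"
  rec
}

#' @export
print.gw_record <- function(x, ...) {
  cat(sprintf(
    "entropic GW record: eps = %.4g, GWD = %.6g (entropic %.6g), %d outer iterations%s\n",
    x$epsilon, x$gwd_plain, x$gwd_entropic, x$n_iterations,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Hyperparameter sweep over the entropy-regularization weight
#'
#' Runs [entropic_gw()] once per trial. Trial `t` uses the `t`-th value of the
#' logarithmically spaced grid of `n_trials` epsilon values on
#' `[eps_min, eps_max]` together with a fresh [random_coupling()]
#' initialization whose seed is derived deterministically from `seed` and `t`.
#' Because the entropic GW problem is non-convex, each trial lands in a local
#' optimum; the sweep keeps them all and marks as optimal the converged record
#' with the smallest plain (unregularized) GW objective — ties broken toward
#' smaller epsilon, then smaller trial index.
#'
#' The defaults mirror the usual protocol for similarity-structure alignment:
#' epsilon from `1e-4` to `1e-1` with logarithmic spacing, one random
#' initialization per epsilon value.
#'
#' @inheritParams entropic_gw
#' @param eps_min,eps_max Sweep range, `0 < eps_min < eps_max`.
#' @param n_trials Number of trials (grid size), >= 1.
#' @param seed Master seed for the per-trial initializations.
#' @param labels1,labels2 Optional item labels; when both are given, each
#'   record also carries the matching rate of its plan (evaluation only —
#'   labels play no role in the optimization).
#' @param polish Number of leading candidates to refine after the sweep:
#'   each is re-run from its own plan with a larger iteration budget and no
#'   annealed restart, so descents truncated by the per-trial cap reach their
#'   stationary point. `0` disables refinement.
#' @param ... Passed on to [entropic_gw()].
#' @return A `gw_sweep` object: list with `records` (list of `gw_record`) and
#'   `optimal_index`.
#' @export
gw_sweep <- function(D, Dp, eps_min = 1e-4, eps_max = 1e-1, n_trials = 500,
                     seed = 1, labels1 = NULL, labels2 = NULL, polish = 1L,
                     ...) {
  stopifnot(eps_min > 0, eps_min < eps_max, n_trials >= 1)
  n <- nrow(as_plain_matrix(D))
  m <- nrow(as_plain_matrix(Dp))
  eps_grid <- if (n_trials == 1) eps_min else {
    exp(seq(log(eps_min), log(eps_max), length.out = n_trials))
  }
  records <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    st <- derive_seed(seed, t)
    init <- random_coupling(n, m, st)
    rec <- entropic_gw(D, Dp, epsilon = eps_grid[t], init = init, ...)
    rec$seed <- st
    if (!is.null(labels1) && !is.null(labels2)) {
      rec$matching_rate <- matching_rate(rec$plan, labels1,
                                         labels2)$matching_rate
    }
    records[[t]] <- rec
  }
  if (!any(vapply(records, `[[`, logical(1), "converged"))) {
    warning("no trial converged; consider widening the epsilon range or ",
            "raising max_outer", call. = FALSE)
  }
  # selection is by the plain objective over every trial: each recorded plan
  # is a feasible coupling, so its objective value is valid whether or not
  # the trial hit the stationarity tolerance
  gwd <- vapply(records, `[[`, numeric(1), "gwd_plain")
  eps <- vapply(records, `[[`, numeric(1), "epsilon")
  best <- order(gwd, eps, seq_along(records))[1]
  # polish the leading candidates: trials at small epsilon can hit the
  # iteration cap mid-descent, so re-run the best few plans with a larger
  # budget and no annealed restart (stay in each plan's basin)
  pol_args <- list(...)
  pol_args$max_outer <- max(5000, if (is.null(pol_args$max_outer)) 0 else
    pol_args$max_outer)
  pol_args$anneal <- FALSE
  for (idx in utils::head(order(gwd, eps, seq_along(records)),
                          max(0L, as.integer(polish)))) {
    inc <- records[[idx]]
    pol <- do.call(entropic_gw, c(list(D = D, Dp = Dp,
                                       epsilon = inc$epsilon,
                                       init = inc$plan), pol_args))
    if (pol$gwd_plain < inc$gwd_plain) {
      inc$plan <- pol$plan
      inc$gwd_plain <- pol$gwd_plain
      inc$gwd_entropic <- pol$gwd_entropic
      inc$converged <- pol$converged
      if (!is.null(labels1) && !is.null(labels2)) {
        inc$matching_rate <- matching_rate(pol$plan, labels1,
                                           labels2)$matching_rate
      }
      records[[idx]] <- inc
    }
  }
  gwd <- vapply(records, `[[`, numeric(1), "gwd_plain")
  best <- order(gwd, eps, seq_along(records))[1]
  structure(list(records = records, optimal_index = best,
                 eps_grid = eps_grid, seed = seed),
            class = "gw_sweep")
}

#' @export
print.gw_sweep <- function(x, ...) {
  opt <- x$records[[x$optimal_index]]
  cat(sprintf(
    "GW sweep: %d trials, eps in [%.3g, %.3g]; optimum at eps = %.4g, GWD = %.6g\n",
    length(x$records), min(x$eps_grid), max(x$eps_grid), opt$epsilon,
    opt$gwd_plain))
  invisible(x)
}

#' Select the sweep optimum
#'
#' Returns the record chosen by the sweep: the trial minimizing the plain GW
#' objective (the entropy term is dropped for model selection, so trials run
#' at different epsilon values are comparable). Every recorded plan is a
#' feasible coupling, so trials that stopped at the iteration cap still
#' compete; `converged` is reported as a per-trial diagnostic.
#'
#' @param result A `gw_sweep` object.
#' @return The optimal `gw_record`.
#' @export
select_optimum <- function(result) {
  stopifnot(inherits(result, "gw_sweep"))
  if (length(result$records) == 0 || is.na(result$optimal_index)) {
    stop("sweep has no records", call. = FALSE)
  }
  result$records[[result$optimal_index]]
}

#' Per-trial sweep table
#'
#' One row per trial: `epsilon`, `seed`, `gwd_entropic`, `gwd_plain`,
#' `matching_rate` (`NA` when labels were not supplied), `n_iterations`,
#' `converged` — the data behind GWD-versus-epsilon diagnostic plots.
#'
#' @param result A `gw_sweep` object.
#' @return A data frame.
#' @export
sweep_table <- function(result) {
  stopifnot(inherits(result, "gw_sweep"))
  recs <- result$records
  data.frame(
    epsilon = vapply(recs, `[[`, numeric(1), "epsilon"),
    seed = vapply(recs, `[[`, integer(1), "seed"),
    gwd_entropic = vapply(recs, `[[`, numeric(1), "gwd_entropic"),
    gwd_plain = vapply(recs, `[[`, numeric(1), "gwd_plain"),
    matching_rate = vapply(recs, function(r) {
      if (is.null(r$matching_rate)) NA_real_ else r$matching_rate
    }, numeric(1)),
    n_iterations = vapply(recs, `[[`, integer(1), "n_iterations"),
    converged = vapply(recs, `[[`, logical(1), "converged")
  )
}
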