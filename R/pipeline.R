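#' All-pairs comparison of dissimilarity structures
#'
#' The end-to-end analysis surface: every input matrix is normalized to
#' `[0, 1]`, the supervised comparison (Spearman correlation of upper
#' triangles) is computed for all unordered pairs of structures, and the
#' unsupervised comparison (epsilon sweep of the entropic GW solver, optimum
#' selected by plain GWD, matching rate of the optimal plan) for all ordered
#' pairs. Optionally writes the full report tree to disk. Fully reproducible
#' from `seed`.
#'
#' @param structures Named list of `dissim` objects with equal item counts,
#'   or a directory path containing matrix CSV files (read with
#'   [read_dissim_csv()]; file stems become structure names).
#' @param eps_min,eps_max,n_trials Sweep configuration (see [gw_sweep()]).
#' @param seed Master seed; the sweep for ordered pair `(i, j)` uses a seed
#'   derived deterministically from it.
#' @param embed_dim Dimensionality of the diagnostic embeddings (>= 2).
#' @param output_dir Optional directory: writes `report.json`,
#'   `spearman.csv`, `matching.csv`, and per-ordered-pair subdirectories with
#'   `sweep.csv`, `plan.csv`, `embeddings.csv`, `rotation.json`.
#' @return A `comparison_report`: list with `names`, `spearman` (symmetric
#'   matrix), `matching` (directed matrix, source rows), `optima` (data frame
#'   of per-pair optimal epsilon/GWD/rate), `chance_level`, `sweeps`,
#'   `embeddings`.
#' @export
run_comparison <- function(structures, eps_min = 1e-4, eps_max = 1e-1,
                           n_trials = 50, seed = 1, embed_dim = 3,
                           output_dir = NULL) {
  if (is.character(structures) && length(structures) == 1) {
    files <- sort(list.files(structures, pattern = "\\.csv$",
                             full.names = TRUE))
    if (length(files) < 2) stop("need at least 2 matrix CSVs in ",
                                structures, call. = FALSE)
    structures <- stats::setNames(lapply(files, read_dissim_csv),
                                  sub("\\.csv$", "", basename(files)))
  }
  stopifnot(is.list(structures), length(structures) >= 2, embed_dim >= 2,
            eps_min < eps_max, n_trials >= 1)
  if (is.null(names(structures)) || anyDuplicated(names(structures))) {
    stop("structures must be uniquely named", call. = FALSE)
  }
  ns <- vapply(structures, nrow, integer(1))
  if (length(unique(ns)) != 1) {
    stop("structures have mismatched item counts: ",
         paste(ns, collapse = ", "), call. = FALSE)
  }
  n <- ns[[1]]
  structures <- lapply(structures, normalize_dissim)
  nm <- names(structures)
  ks <- length(nm)

  spearman <- matrix(NA_real_, ks, ks, dimnames = list(nm, nm))
  diag(spearman) <- 1
  for (i in seq_len(ks - 1)) {
    for (j in seq((i + 1), ks)) {
      # supervised comparison needs a shared label order
      Dj <- structures[[j]]
      Di <- structures[[i]]
      if (!identical(dissim_labels(Di), dissim_labels(Dj))) {
        ord <- match(dissim_labels(Di), dissim_labels(Dj))
        if (anyNA(ord)) {
          stop("structures ", nm[i], " and ", nm[j],
               " do not share labels; supervised comparison undefined",
               call. = FALSE)
        }
        Dj <- dissim_matrix(as_plain_matrix(Dj)[ord, ord],
                            labels = dissim_labels(Di),
                            normalized = TRUE)
      }
      spearman[i, j] <- spearman[j, i] <- rsa_spearman(Di, Dj)
    }
  }

  embeddings <- lapply(seq_along(structures), function(i) {
    mds_embed(structures[[i]], dim = embed_dim,
              seed = derive_seed(seed, 10000 + i))
  })
  names(embeddings) <- nm

  matching <- matrix(NA_real_, ks, ks, dimnames = list(nm, nm))
  optima <- list()
  sweeps <- list()
  pair_id <- 0L
  for (i in seq_len(ks)) {
    for (j in seq_len(ks)) {
      if (i == j) next
      pair_id <- pair_id + 1L
      sw <- gw_sweep(structures[[i]], structures[[j]],
                     eps_min = eps_min, eps_max = eps_max,
                     n_trials = n_trials,
                     seed = derive_seed(seed, pair_id),
                     labels1 = dissim_labels(structures[[i]]),
                     labels2 = dissim_labels(structures[[j]]))
      opt <- select_optimum(sw)
      mr <- matching_rate(opt$plan, dissim_labels(structures[[i]]),
                          dissim_labels(structures[[j]]))
      matching[i, j] <- mr$matching_rate
      key <- paste0(nm[i], "->", nm[j])
      sweeps[[key]] <- sw
      optima[[key]] <- data.frame(
        source = nm[i], target = nm[j],
        epsilon = opt$epsilon, gwd = opt$gwd_plain,
        matching_rate = mr$matching_rate,
        stringsAsFactors = FALSE
      )
    }
  }
  optima <- do.call(rbind, c(optima, list(make.row.names = FALSE)))

  report <- structure(list(
    names = nm, n_items = n, spearman = spearman, matching = matching,
    optima = optima, chance_level = 100 / n, sweeps = sweeps,
    embeddings = embeddings,
    config = list(eps_min = eps_min, eps_max = eps_max,
                  n_trials = n_trials, seed = seed, embed_dim = embed_dim)
  ), class = "comparison_report")

  if (!is.null(output_dir)) write_comparison_report(report, structures,
                                                    output_dir)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Comparison of %d structures (%d items; chance %.2f%%)\n",
              length(x$names), x$n_items, x$chance_level))
  cat("Spearman rho (upper triangles):\n")
  print(round(x$spearman, 3))
  cat("Matching rate %% (rows = source):\n")
  print(round(x$matching, 2))
  invisible(x)
}

write_comparison_report <- function(report, structures, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$spearman,
                   file.path(output_dir, "spearman.csv"))
  utils::write.csv(report$matching,
                   file.path(output_dir, "matching.csv"))
  jsonlite::write_json(
    list(names = report$names, n_items = report$n_items,
         chance_level = report$chance_level, optima = report$optima,
         config = report$config),
    file.path(output_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (key in names(report$sweeps)) {
    sub <- file.path(output_dir, gsub("->", "_to_", key, fixed = TRUE))
    dir.create(sub, showWarnings = FALSE)
    sw <- report$sweeps[[key]]
    utils::write.csv(sweep_table(sw), file.path(sub, "sweep.csv"),
                     row.names = FALSE)
    opt <- select_optimum(sw)
    src <- sub("->.*$", "", key)
    tgt <- sub("^.*->", "", key)
    plan <- unclass(opt$plan)
    dimnames(plan) <- list(dissim_labels(structures[[src]]),
                           dissim_labels(structures[[tgt]]))
    utils::write.csv(plan, file.path(sub, "plan.csv"))
    rot <- procrustes_align(report$embeddings[[src]],
                            report$embeddings[[tgt]], opt$plan)
    emb <- data.frame(
      label = c(report$embeddings[[src]]$labels,
                report$embeddings[[tgt]]$labels),
      structure = c(rep(src, length(report$embeddings[[src]]$labels)),
                    rep(tgt, length(report$embeddings[[tgt]]$labels))),
      t(cbind(report$embeddings[[src]]$coords, rot$aligned))
    )
    names(emb)[-(1:2)] <- paste0("dim", seq_len(nrow(rot$Q)))
    utils::write.csv(emb, file.path(sub, "embeddings.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(Q = rot$Q, residual = rot$residual),
                         file.path(sub, "rotation.json"),
                         digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  }
  invisible(output_dir)
}

#' Synthetic validation suite
#'
#' Runs the three ground-truthed scenario families against the alignment
#' pipeline and tabulates one row per (scenario, seed):
#' \describe{
#'   \item{recovery}{permuted noisy copy of a Euclidean structure — the
#'     sweep optimum should recover the planted permutation.}
#'   \item{noise}{same, across increasing noise levels — matching should
#'     degrade toward chance.}
#'   \item{dissociation}{category pair with resampled fine structure — high
#'     Spearman correlation should coexist with chance-level matching.}
#' }
#'
#' @param seeds Integer vector of replicate seeds.
#' @param n Item count for the recovery/noise scenarios.
#' @param noise_levels Noise standard deviations (relative to the mean
#'   off-diagonal dissimilarity) for the noise scenario.
#' @param n_trials Sweep trials per replicate.
#' @param eps_min,eps_max Sweep range.
#' @param category_args List of arguments for [make_category_pair()] in the
#'   dissociation scenario.
#' @return Data frame with columns `scenario`, `seed`, `noise`,
#'   `spearman_rho`, `matching_rate`, `chance_level`, `gwd`.
#' @export
run_synthetic_validation <- function(seeds = 1:5, n = 20,
                                     noise_levels = c(0, 0.1, 0.3),
                                     n_trials = 20, eps_min = 1e-4,
                                     eps_max = 1e-1,
                                     category_args = list()) {
  rows <- list()
  add_row <- function(scenario, seed, noise, pair) {
    src <- normalize_dissim(pair$source)
    tgt <- normalize_dissim(pair$target)
    sw <- gw_sweep(src, tgt, eps_min = eps_min, eps_max = eps_max,
                   n_trials = n_trials, seed = derive_seed(seed, 777))
    opt <- select_optimum(sw)
    mr <- matching_rate(opt$plan, dissim_labels(src), dissim_labels(tgt))
    # supervised comparison in the ground-truth order
    ord <- match(dissim_labels(src), dissim_labels(tgt))
    tgt_o <- dissim_matrix(as_plain_matrix(tgt)[ord, ord],
                           labels = dissim_labels(src), normalized = TRUE)
    rows[[length(rows) + 1]] <<- data.frame(
      scenario = scenario, seed = seed, noise = noise,
      spearman_rho = rsa_spearman(src, tgt_o),
      matching_rate = mr$matching_rate,
      chance_level = 100 / mr$n_items,
      gwd = opt$gwd_plain, stringsAsFactors = FALSE)
  }
  for (s in seeds) {
    base <- sample_structure(n, seed = derive_seed(s, 1))$dissim
    rel <- mean(upper_entries(base))
    add_row("recovery", s, 0, make_pair(base, 0, seed = derive_seed(s, 2)))
    for (nl in noise_levels) {
      add_row("noise", s, nl,
              make_pair(base, nl * rel, seed = derive_seed(s, 3)))
    }
    add_row("dissociation", s, 0,
            do.call(make_category_pair,
                    c(list(resample_fine = TRUE, seed = derive_seed(s, 4)),
                      category_args)))
  }
  do.call(rbind, rows)
}
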