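#' Matching rate of a transportation plan
#'
#' External-label evaluation of an unsupervised alignment. Source item `i`
#' counts as a match when the argmax over target items of its coupling row
#' points to a target item carrying the same label; the matching rate is the
#' percentage of source items that match. Labels are used only here — never
#' during optimization. For `n` distinct shared labels the chance level is
#' `100/n`.
#'
#' Argmax ties are broken toward the smallest target index and flagged in the
#' report (strictly positive entropic plans make exact ties measure-zero, but
#' degenerate inputs can produce them). Duplicate labels are permitted: a
#' match requires label equality, not index equality.
#'
#' @param plan A `transport_plan` (or plain coupling matrix), `n x m`.
#' @param labels1 Character vector of `n` source labels.
#' @param labels2 Character vector of `m` target labels.
#' @param top_k Optional integer vector; for each `k`, also report the
#'   percentage of source items whose top-`k` coupling entries contain the
#'   matching label.
#' @return A `matching_report`: list with `matching_rate` (percent),
#'   `per_item_match` (named logical), `n_items`, `chance_level` (`100/n`
#'   when all labels are distinct and the label sets coincide, else `NA`),
#'   `tie_flags`, and `top_k_rates` when requested.
#' @export
matching_rate <- function(plan, labels1, labels2, top_k = NULL) {
  G <- unclass(plan)
  labels1 <- as.character(labels1)
  labels2 <- as.character(labels2)
  if (length(labels1) != nrow(G) || length(labels2) != ncol(G)) {
    stop("label lengths do not match plan dimensions", call. = FALSE)
  }
  n <- nrow(G)
  amax <- max.col(G, ties.method = "first")
  rowmax <- G[cbind(seq_len(n), amax)]
  ties <- rowSums(G == rowmax) > 1
  match_i <- labels2[amax] == labels1
  rate <- 100 * sum(match_i) / n
  chance <- if (!anyDuplicated(labels1) && !anyDuplicated(labels2) &&
                setequal(labels1, labels2)) 100 / n else NA_real_
  rep <- list(
    matching_rate = rate,
    per_item_match = stats::setNames(match_i, labels1),
    n_items = n,
    chance_level = chance,
    tie_flags = stats::setNames(ties, labels1)
  )
  if (!is.null(top_k)) {
    rep$top_k_rates <- vapply(top_k, function(k) {
      hits <- vapply(seq_len(n), function(i) {
        ord <- order(G[i, ], decreasing = TRUE)[seq_len(min(k, ncol(G)))]
        labels1[i] %in% labels2[ord]
      }, logical(1))
      100 * mean(hits)
    }, numeric(1))
    names(rep$top_k_rates) <- top_k
  }
  class(rep) <- "matching_report"
  rep
}

#' @export
print.matching_report <- function(x, ...) {
  cat(sprintf("Matching rate: %.2f%% (%d/%d items; chance %s)\n",
              x$matching_rate, sum(x$per_item_match), x$n_items,
              if (is.na(x$chance_level)) "undefined"
              else sprintf("%.2f%%", x$chance_level)))
  invisible(x)
}

#' Representational similarity analysis (Spearman, upper triangles)
#'
#' The conventional supervised comparison of two dissimilarity matrices:
#' Spearman rank correlation between their strict upper-triangular entries.
#' This statistic inherently assumes that item `i` in one structure
#' corresponds to item `i` in the other, so both matrices must carry the same
#' labels in the same order. Ties receive average (fractional) ranks.
#'
#' @param D,Dp `dissim` objects with identical labels in identical order,
#'   `n >= 3`.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
rsa_spearman <- function(D, Dp) {
  stopifnot(is_dissim(D), is_dissim(Dp))
  if (nrow(D) < 3) stop("need at least 3 items", call. = FALSE)
  if (!identical(dissim_labels(D), dissim_labels(Dp))) {
    stop("labels differ or are ordered differently; this supervised ",
         "statistic assumes an item correspondence by label", call. = FALSE)
  }
  stats::cor(upper_entries(D), upper_entries(Dp), method = "spearman")
}
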