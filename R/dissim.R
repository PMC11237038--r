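#' Labeled dissimilarity matrix
#'
#' Constructs a validated dissimilarity matrix: a square, symmetric,
#' nonnegative matrix with a zero diagonal and unique item labels. This is the
#' container shared by every stage of the alignment workflow (the `D` and `D'`
#' of the Gromov-Wasserstein objective).
#'
#' Symmetry is checked against `tol` and then enforced exactly by averaging the
#' matrix with its transpose, so downstream code can rely on exact symmetry.
#'
#' @param values Numeric `n x n` matrix of pairwise dissimilarities.
#' @param labels Character vector of `n` unique item identifiers. Defaults to
#'   the row names of `values`, or `item1..itemn` when absent.
#' @param normalized Logical; `TRUE` marks the matrix as scaled to `[0, 1]`
#'   (max entry 1 unless all-zero). Validated when set.
#' @param tol Numeric tolerance for the symmetry and zero-diagonal checks.
#' @return An object of class `dissim`: the numeric matrix with `labels` as
#'   dimnames and a `normalized` attribute.
#' @examples
#' m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
#' d <- dissim_matrix(m, labels = c("a", "b", "c"))
#' dissim_labels(d)
#' @export
dissim_matrix <- function(values, labels = NULL, normalized = FALSE,
                          tol = 1e-9) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(values)
  if (ncol(values) != n) {
    stop("dissimilarity matrix must be square; got ", n, " x ", ncol(values),
         call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("item", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("need exactly ", n, " labels, got ", length(labels), call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("dissimilarity values must be finite", call. = FALSE)
  }
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    stop("matrix is asymmetric beyond tolerance (max |D - t(D)| = ",
         format(asym), ")", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  if (max(abs(diag(values))) > tol) {
    stop("diagonal entries must be zero", call. = FALSE)
  }
  diag(values) <- 0
  if (min(values) < -tol) {
    stop("dissimilarities must be nonnegative", call. = FALSE)
  }
  values[values < 0] <- 0
  if (normalized) {
    mx <- max(values)
    if (mx > 0 && abs(mx - 1) > tol) {
      stop("matrix flagged normalized but max entry is ", format(mx),
           call. = FALSE)
    }
  }
  dimnames(values) <- list(labels, labels)
  structure(values, normalized = normalized, class = c("dissim", "matrix"))
}

#' @export
print.dissim <- function(x, ...) {
  cat(sprintf("Dissimilarity matrix: %d items%s\n", nrow(x),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @rdname dissim_matrix
#' @param D A `dissim` object.
#' @export
dissim_labels <- function(D) rownames(D)

#' @rdname dissim_matrix
#' @param x Object to test.
#' @export
is_dissim <- function(x) inherits(x, "dissim")

# strip class/attrs down to a plain matrix
as_plain_matrix <- function(D) {
  m <- unclass(D)
  attr(m, "normalized") <- NULL
  m
}

#' Aggregate a long-format rating table into a dissimilarity matrix
#'
#' Pools every rating for an unordered item pair (across raters/trials and
#' both orderings of the pair) into its arithmetic mean, the way a
#' group-average similarity-judgment matrix is built from many raters. The
#' diagonal is forced to zero even when same-item ratings are present.
#'
#' @param table Data frame with columns `item_a`, `item_b`, `rating` and
#'   optionally `rater` (ignored by the mean; kept for provenance).
#' @param scale_max Upper bound of the rating scale (default 7; ratings must
#'   lie in `[0, scale_max]`).
#' @param labels Optional character vector fixing item order; defaults to
#'   order of first appearance in the table.
#' @return A `dissim` object with `normalized = FALSE`.
#' @export
dissim_from_ratings <- function(table, scale_max = 7, labels = NULL) {
  need <- c("item_a", "item_b", "rating")
  if (!all(need %in% names(table))) {
    stop("rating table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  a <- as.character(table$item_a)
  b <- as.character(table$item_b)
  r <- as.numeric(table$rating)
  if (any(!is.finite(r)) || any(r < 0) || any(r > scale_max)) {
    stop("ratings must lie in [0, ", scale_max, "]", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- unique(as.vector(rbind(a, b)))
  } else if (!all(c(a, b) %in% labels)) {
    stop("rating table contains items not in `labels`", call. = FALSE)
  }
  n <- length(labels)
  ia <- match(a, labels)
  ib <- match(b, labels)
  off <- ia != ib
  lo <- pmin(ia, ib)[off]
  hi <- pmax(ia, ib)[off]
  key <- (lo - 1L) * n + hi
  sums <- tapply(r[off], key, sum)
  cnts <- tapply(r[off], key, length)
  m <- matrix(0, n, n)
  idx <- as.integer(names(sums))
  klo <- (idx - 1L) %/% n + 1L
  khi <- idx - (klo - 1L) * n
  have <- matrix(FALSE, n, n)
  have[cbind(klo, khi)] <- TRUE
  miss <- which(upper.tri(have) & !have, arr.ind = TRUE)
  if (nrow(miss) > 0) {
    stop("no rating for pair {", labels[miss[1, 1]], ", ",
         labels[miss[1, 2]], "}", call. = FALSE)
  }
  m[cbind(klo, khi)] <- sums / cnts
  m <- m + t(m)
  dissim_matrix(m, labels = labels, normalized = FALSE)
}

#' Scale a dissimilarity matrix to the unit interval
#'
#' Divides every entry by the maximum entry so values range between 0 and 1
#' (the convention used before computing Gromov-Wasserstein distances, so that
#' structures measured on different rating scales are comparable). The
#' all-zero matrix is returned unchanged. Idempotent.
#'
#' @param D A `dissim` object.
#' @return A `dissim` object with `normalized = TRUE` and max entry 1 (unless
#'   all-zero).
#' @export
normalize_dissim <- function(D) {
  stopifnot(is_dissim(D))
  m <- as_plain_matrix(D)
  mx <- max(m)
  if (mx > 0) m <- m / mx
  dissim_matrix(m, labels = dissim_labels(D), normalized = TRUE)
}

#' Read / write a dissimilarity matrix as CSV
#'
#' The on-disk format is a header row of item labels followed by the `n x n`
#' numeric body (comma separator, `.` decimal, no row-name column). Writing
#' then reading reproduces labels and values to machine precision.
#'
#' @param path File path.
#' @return `read_dissim_csv` returns a `dissim`; `write_dissim_csv` returns
#'   `path` invisibly.
#' @export
read_dissim_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, header = TRUE)
  labels <- names(df)
  if (anyDuplicated(labels)) {
    stop("duplicate label in header of ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) != length(labels)) {
    stop("non-square matrix in ", path, ": ", length(labels), " columns but ",
         nrow(df), " rows", call. = FALSE)
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("non-numeric entries in ", path, call. = FALSE)
  }
  dissim_matrix(as.matrix(df), labels = labels)
}

#' @rdname read_dissim_csv
#' @param D A `dissim` object to write.
#' @export
write_dissim_csv <- function(D, path) {
  stopifnot(is_dissim(D))
  m <- as_plain_matrix(D)
  out <- rbind(dissim_labels(D), format(m, digits = 17, trim = TRUE,
                                        scientific = FALSE))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

# off-diagonal upper-triangle entries as a vector (row-major pair order)
upper_entries <- function(D) {
  m <- as_plain_matrix(D)
  m[upper.tri(m)]
}
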