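#' Parse HEX color codes
#'
#' Accepts `"#RRGGBB"` or `"RRGGBB"`, case-insensitive.
#'
#' @param code Character vector of hex codes.
#' @return An `n x 3` integer matrix with columns `r`, `g`, `b` in
#'   `[0, 255]`.
#' @examples
#' parse_hex(c("#FFFFFF", "ff0000"))
#' @export
parse_hex <- function(code) {
  code <- as.character(code)
  ok <- grepl("^#?[0-9a-fA-F]{6}$", code)
  if (!all(ok)) {
    stop("malformed hex code: ", paste(code[!ok], collapse = ", "),
         call. = FALSE)
  }
  code <- sub("^#", "", code)
  rgb <- cbind(
    r = strtoi(substr(code, 1, 2), 16L),
    g = strtoi(substr(code, 3, 4), 16L),
    b = strtoi(substr(code, 5, 6), 16L)
  )
  storage.mode(rgb) <- "integer"
  rgb
}

#' Color set with RGB and CIELAB coordinates
#'
#' Builds the stimulus container used by the color-space baseline models:
#' hex labels, their sRGB triples, and CIELAB coordinates derived by the
#' standard sRGB (D65, 2\eqn{^\circ} observer) transform.
#'
#' @param hex Character vector of hex codes (must be unique).
#' @return A `color_set`: list with `labels` (normalized `"#RRGGBB"`), `rgb`
#'   (`n x 3` integer), `lab` (`n x 3` numeric).
#' @export
color_set <- function(hex) {
  rgb <- parse_hex(hex)
  labels <- toupper(paste0("#", sub("^#", "", as.character(hex))))
  if (anyDuplicated(labels)) stop("duplicate colors in the set",
                                  call. = FALSE)
  structure(list(labels = labels, rgb = rgb, lab = srgb_to_lab(rgb)),
            class = "color_set")
}

#' @export
print.color_set <- function(x, ...) {
  cat(sprintf("Color set: %d colors (%s%s)\n", length(x$labels),
              paste(utils::head(x$labels, 4), collapse = ", "),
              if (length(x$labels) > 4) ", ..." else ""))
  invisible(x)
}

#' sRGB to CIELAB conversion
#'
#' IEC 61966-2-1 inverse companding, the sRGB linear-RGB-to-XYZ matrix, and
#' the CIE XYZ-to-Lab transform under the D65 white point (2\eqn{^\circ}
#' observer).
#'
#' @param rgb Integer vector of length 3 or `n x 3` matrix, channels in
#'   `[0, 255]`.
#' @return An `n x 3` matrix with columns `L`, `a`, `b`.
#' @export
srgb_to_lab <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, nrow = 1)
  if (ncol(rgb) != 3 || any(!is.finite(rgb)) || any(rgb < 0) ||
      any(rgb > 255)) {
    stop("rgb channels must lie in [0, 255]", call. = FALSE)
  }
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              3, 3, byrow = TRUE)
  xyz <- lin %*% t(m)
  white <- c(0.95047, 1.00000, 1.08883)  # D65
  t3 <- sweep(xyz, 2, white, `/`)
  eps <- (6 / 29)^3
  f <- ifelse(t3 > eps, t3^(1 / 3), t3 / (3 * (6 / 29)^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' CIEDE2000 color difference
#'
#' The CIE's 2000 perceptual color-difference formula \eqn{\Delta E_{00}} on
#' CIELAB coordinates, including the chroma-dependent `G` correction of
#' `a*`, the lightness/chroma/hue weighting functions `S_L`, `S_C`, `S_H`,
#' and the blue-region rotation term `R_T`, with parametric factors
#' `kL = kC = kH = 1` by default. Hue angles are handled per the published
#' discontinuity rules (hue undefined at zero chroma).
#'
#' @param lab1,lab2 Numeric length-3 Lab triples (or `n x 3` matrices,
#'   compared row-wise).
#' @param kL,kC,kH Parametric weighting factors.
#' @return Numeric vector of \eqn{\Delta E_{00}} values.
#' @export
ciede2000 <- function(lab1, lab2, kL = 1, kC = 1, kH = 1) {
  if (is.null(dim(lab1))) lab1 <- matrix(lab1, nrow = 1)
  if (is.null(dim(lab2))) lab2 <- matrix(lab2, nrow = 1)
  stopifnot(ncol(lab1) == 3, ncol(lab2) == 3, nrow(lab1) == nrow(lab2))
  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]
  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)
  h1p <- ifelse(C1p == 0, 0, (atan2(b1, a1p) * 180 / pi) %% 360)
  h2p <- ifelse(C2p == 0, 0, (atan2(b2, a2p) * 180 / pi) %% 360)
  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
                ifelse(abs(dh) <= 180, dh,
                       ifelse(dh > 180, dh - 360, dh + 360)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * pi / 180)
  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
                ifelse(abs(h1p - h2p) <= 180, hsum / 2,
                       ifelse(hsum < 360, (hsum + 360) / 2,
                              (hsum - 360) / 2)))
  T_ <- 1 - 0.17 * cos((hbp - 30) * pi / 180) +
    0.24 * cos(2 * hbp * pi / 180) +
    0.32 * cos((3 * hbp + 6) * pi / 180) -
    0.20 * cos((4 * hbp - 63) * pi / 180)
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * T_
  RT <- -sin(2 * dtheta * pi / 180) * RC
  sqrt((dLp / (kL * SL))^2 + (dCp / (kC * SC))^2 + (dHp / (kH * SH))^2 +
         RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}

#' RGB-space dissimilarity matrix
#'
#' Entry `(i, j)` is the Euclidean distance between the two colors' sRGB
#' triples in the 3-dimensional RGB cube — the simplest color-space baseline
#' model.
#'
#' @param colors A `color_set` with `n >= 2` colors.
#' @return A `dissim` object labeled by hex codes.
#' @export
rgb_dissimilarity <- function(colors) {
  stopifnot(inherits(colors, "color_set"), length(colors$labels) >= 2)
  d <- as.matrix(stats::dist(colors$rgb))
  dissim_matrix(d, labels = colors$labels)
}

#' CIELAB/CIEDE2000 dissimilarity matrix
#'
#' Entry `(i, j)` is the CIEDE2000 difference between the two colors' CIELAB
#' coordinates — the perceptually weighted color-space baseline model.
#'
#' @inheritParams rgb_dissimilarity
#' @return A `dissim` object labeled by hex codes.
#' @export
lab_dissimilarity <- function(colors) {
  stopifnot(inherits(colors, "color_set"), length(colors$labels) >= 2)
  n <- nrow(colors$lab)
  d <- matrix(0, n, n)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  d[idx] <- ciede2000(colors$lab[idx[, 1], , drop = FALSE],
                      colors$lab[idx[, 2], , drop = FALSE])
  d <- d + t(d)
  dissim_matrix(d, labels = colors$labels)
}

#' Random color sample
#'
#' Draws `n` distinct colors uniformly from the sRGB cube — a stand-in
#' stimulus set for exercising the color-space baseline models when no
#' experimental color list is supplied.
#'
#' @param n Number of colors.
#' @param seed Integer seed.
#' @return A `color_set`.
#' @export
random_colors <- function(n, seed) {
  hex <- with_local_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      cand <- sprintf("#%02X%02X%02X",
                      sample.int(256, n, replace = TRUE) - 1L,
                      sample.int(256, n, replace = TRUE) - 1L,
                      sample.int(256, n, replace = TRUE) - 1L)
      out <- unique(c(out, cand))
    }
    out[seq_len(n)]
  })
  color_set(hex)
}
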