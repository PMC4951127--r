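#' Munsell chip lookup tables bundled with the package
#'
#' Two hue-by-chroma lookup tables map Munsell chips to CIE xyY coordinates:
#' `"value6"` holds the 27 full-range chips (5Y through 10P, value 6,
#' chroma 8) used for the English reconstruction study, and
#' `"value5_synthetic"` holds a clearly-labelled synthetic stand-in for the
#' 19 chips (5Y through 10B, value 5, chroma 8) spanning the cross-language
#' discrimination spectrum; its chromaticities are carried over from the
#' value-6 chips of the same hue and its luminance factor is the Munsell
#' value-5 luminance factor (Y = 19.77). See the package vignette for the
#' provenance discussion.
#'
#' @param table Which bundled table to load: `"value6"` or
#'   `"value5_synthetic"`.
#' @return A data frame with columns `hue`, `value`, `chroma`, `x`, `y`, `Y`.
#' @export
munsell_table <- function(table = c("value6", "value5_synthetic")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("munsell_", table, ".csv"),
                      package = "catadjust", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Look up the xyY coordinates of a Munsell chip
#'
#' @param hue Munsell hue string, e.g. `"7.5BG"`.
#' @param table A lookup data frame as returned by [munsell_table()].
#' @param value,chroma Munsell value and chroma of the requested chip;
#'   defaults taken from the table (which is constant in both).
#' @return A named numeric vector `c(x, y, Y)`.
#' @export
munsell_to_xyy <- function(hue, table, value = NULL, chroma = NULL) {
  stopifnot(is.character(hue), length(hue) >= 1L)
  if (is.null(value)) value <- table$value[1L]
  if (is.null(chroma)) chroma <- table$chroma[1L]
  idx <- match(paste(hue, value, chroma),
               paste(table$hue, table$value, table$chroma))
  if (anyNA(idx)) {
    missing <- hue[is.na(idx)]
    stop("Munsell chip(s) not in lookup table: ",
         paste(sprintf("%s value %s chroma %s", missing, value, chroma),
               collapse = ", "), call. = FALSE)
  }
  out <- as.matrix(table[idx, c("x", "y", "Y")])
  rownames(out) <- hue
  if (length(hue) == 1L) out <- c(x = out[1, 1], y = out[1, 2], Y = out[1, 3])
  out
}

#' CIE D65 white point (2-degree observer)
#'
#' Standard D65 chromaticity with the luminance factor set to 100, the scale
#' on which the stimulus luminance factors are expressed.
#'
#' @return Named vector `c(x, y, Y)`.
#' @export
d65_white <- function() c(x = 0.3127, y = 0.3290, Y = 100)

# xyY -> XYZ; rows of a matrix with columns x, y, Y
xyy_to_xyz <- function(xyy) {
  xyy <- rbind(xyy)
  x <- xyy[, 1]; y <- xyy[, 2]; Y <- xyy[, 3]
  if (any(y <= 0)) stop("chromaticity y must be positive", call. = FALSE)
  cbind(X = x * Y / y, Y = Y, Z = (1 - x - y) * Y / y)
}

#' Convert xyY colors to CIELAB
#'
#' Standard CIE 1976 L*a*b* transform relative to a reference white,
#' by default D65 for the 2-degree observer.
#'
#' @param xyy A numeric vector `c(x, y, Y)` or a matrix/data frame with
#'   columns `x`, `y`, `Y` (one color per row).
#' @param white Reference white as `c(x, y, Y)`; `white["Y"]` must be
#'   positive and on the same luminance scale as `xyy[, "Y"]`.
#' @return A matrix with columns `L`, `a`, `b`.
#' @export
xyy_to_lab <- function(xyy, white = d65_white()) {
  if (is.data.frame(xyy)) xyy <- as.matrix(xyy[, c("x", "y", "Y")])
  if (white[["Y"]] <= 0) stop("white point luminance must be positive", call. = FALSE)
  xyz <- xyy_to_xyz(xyy)
  wn <- xyy_to_xyz(rbind(white))[1, ]
  f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  fx <- f(xyz[, "X"] / wn["X"])
  fy <- f(xyz[, "Y"] / wn["Y"])
  fz <- f(xyz[, "Z"] / wn["Z"])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' CIE76 color difference
#'
#' Euclidean distance in CIELAB, the plain delta-E metric.
#'
#' @param a,b CIELAB colors as length-3 vectors `(L, a, b)` or matrices with
#'   one color per row (recycled row-wise).
#' @return Nonnegative numeric vector of distances.
#' @export
delta_e <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  unname(sqrt(rowSums((a - b)^2)))
}

#' Build a unit-length 1-D perceptual spectrum
#'
#' Orders colors along one dimension with neighbor spacing proportional to
#' their CIELAB delta-E, rescaled so the full spectrum has length exactly 1.
#' The input order defines the orientation; for the bundled hue tables the
#' yellow end sits at 0 and the blue/purple end at 1.
#'
#' @param colors A data frame with columns `x`, `y`, `Y` (one color per row,
#'   already ordered along the spectrum), optionally with a `hue` column used
#'   as labels.
#' @param labels Optional character labels, one per color; defaults to the
#'   `hue` column when present.
#' @param white Reference white passed to [xyy_to_lab()].
#' @return An object of class `color_spectrum`: a list with `labels`,
#'   `positions` (strictly increasing, first 0, last 1), `lab` (CIELAB
#'   coordinates), and `anchor` (logical, see [build_color_wheel()]).
#' @export
build_spectrum <- function(colors, labels = NULL, white = d65_white()) {
  if (is.null(labels)) {
    labels <- if (!is.null(colors$hue)) as.character(colors$hue)
              else as.character(seq_len(nrow(colors)))
  }
  if (nrow(colors) < 2L) stop("need at least 2 colors to build a spectrum", call. = FALSE)
  lab <- xyy_to_lab(colors, white = white)
  gaps <- delta_e(lab[-nrow(lab), , drop = FALSE], lab[-1, , drop = FALSE])
  if (any(gaps == 0)) {
    stop("duplicate adjacent colors (zero delta-E gap) at index ",
         paste(which(gaps == 0), collapse = ", "), call. = FALSE)
  }
  pos <- unname(c(0, cumsum(gaps)) / sum(gaps))
  anchor <- if (!is.null(colors$anchor)) as.logical(colors$anchor)
            else rep(TRUE, nrow(colors))
  structure(list(labels = labels, positions = pos, lab = lab, anchor = anchor),
            class = "color_spectrum")
}

#' @export
print.color_spectrum <- function(x, ...) {
  cat(sprintf("<color_spectrum: %d colors (%d anchors), [%s .. %s]>\n",
              length(x$positions), sum(x$anchor),
              x$labels[1], x$labels[length(x$labels)]))
  invisible(x)
}

#' Spectrum position of labelled colors
#'
#' @param spectrum A `color_spectrum`.
#' @param label Character labels (e.g. Munsell hue strings) to resolve.
#' @return Numeric positions in `[0, 1]`.
#' @export
spectrum_position <- function(spectrum, label) {
  idx <- match(label, spectrum$labels)
  if (anyNA(idx)) {
    stop("label(s) not on spectrum: ",
         paste(label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  unname(spectrum$positions[idx])
}

#' Anchor positions of a spectrum as a data frame
#'
#' @param spectrum A `color_spectrum`.
#' @return Data frame with columns `label` and `position`, anchors only.
#' @export
spectrum_anchors <- function(spectrum) {
  data.frame(label = spectrum$labels[spectrum$anchor],
             position = spectrum$positions[spectrum$anchor],
             stringsAsFactors = FALSE)
}

#' Construct a finely discretized response color wheel
#'
#' Supplements ordered anchor colors with `n_interp` points interpolated
#' linearly (independently per channel) in xyY between each neighboring
#' anchor pair, yielding `A + (A - 1) * n_interp` colors in spectrum order.
#'
#' @param anchors Data frame of ordered anchor colors with columns `x`, `y`,
#'   `Y` and optionally `hue`.
#' @param n_interp Number of evenly spaced interpolants per gap (>= 0).
#' @return Data frame with columns `x`, `y`, `Y`, `hue` (NA for
#'   interpolants), and logical `anchor`.
#' @export
build_color_wheel <- function(anchors, n_interp = 25L) {
  stopifnot(nrow(anchors) >= 2L, n_interp >= 0L)
  a <- as.matrix(anchors[, c("x", "y", "Y")])
  hue <- if (!is.null(anchors$hue)) as.character(anchors$hue) else rep(NA_character_, nrow(a))
  rows <- vector("list", 2L * nrow(a) - 1L)
  for (i in seq_len(nrow(a) - 1L)) {
    w <- seq_len(n_interp) / (n_interp + 1L)
    interp <- outer(1 - w, a[i, ]) + outer(w, a[i + 1L, ])
    rows[[2L * i - 1L]] <- cbind(a[i, , drop = FALSE], anchor = 1)
    rows[[2L * i]] <- if (n_interp > 0L) cbind(interp, anchor = 0) else NULL
  }
  rows[[2L * nrow(a) - 1L]] <- cbind(a[nrow(a), , drop = FALSE], anchor = 1)
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("x", "y", "Y", "anchor")
  out$anchor <- out$anchor == 1
  out$hue <- NA_character_
  out$hue[out$anchor] <- hue
  rownames(out) <- NULL
  out
}

#' The full-range English reconstruction spectrum
#'
#' Builds the 677-color response wheel from the 27 value-6 chips (25 xyY
#' interpolants per gap) and lays it out on a unit-length CIELAB spectrum;
#' chip positions are the anchor positions on that wheel-based spectrum.
#'
#' @param n_interp Interpolants per anchor gap (default 25, giving 677 wheel
#'   colors).
#' @return A `color_spectrum` over the full wheel; use [spectrum_anchors()]
#'   or [spectrum_position()] for chip positions.
#' @export
study1_spectrum <- function(n_interp = 25L) {
  chips <- munsell_table("value6")
  wheel <- build_color_wheel(chips, n_interp = n_interp)
  build_spectrum(wheel)
}

#' The cross-language discrimination spectrum
#'
#' The 19 chips from 5Y to 10B (value 5, chroma 8; synthetic xyY stand-in
#' table) spaced by CIELAB delta-E and normalized to unit length.
#'
#' @return A `color_spectrum` with one anchor per chip.
#' @export
study2_spectrum <- function() {
  build_spectrum(munsell_table("value5_synthetic"))
}
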