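# No-reference quality scoring and contrast enhancement.
#
# The published system delegates these two steps to external algorithms
# whose internals are outside this package's scope; the functions below are
# documented surrogates behind the same two-function gate interface, and any
# pair of functions with the same signatures can be swapped in through
# quality_gate().

#' Quality gate parameters
#'
#' @param tau1 quality threshold in \[0, 1\]; slices scoring at or above it
#'   pass unmodified, slices below it are contrast-enhanced first
#'   (default 0.9).
#' @param beta enhancement tuning parameter (sigmoid slope; default 4).
#' @param score_fun,enhance_fun surrogate implementations of the
#'   no-reference score and the enhancement; any functions with signatures
#'   `function(img)` and `function(img, beta)` may be configured.
#' @return object of class `quality_gate`.
#' @export
quality_gate <- function(tau1 = 0.9, beta = 4,
                         score_fun = quality_score, enhance_fun = enhance_contrast) {
  if (tau1 < 0 || tau1 > 1) stop("tau1 must be in [0, 1]", call. = FALSE)
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  structure(list(tau1 = tau1, beta = beta, score_fun = score_fun,
                 enhance_fun = enhance_fun),
            class = "quality_gate")
}

#' No-reference quality score (surrogate)
#'
#' Normalized RMS contrast of the body region: the intensity standard
#' deviation inside the hole-filled Otsu foreground, divided by a
#' calibration constant and clipped to \[0, 1\].  The calibration constant
#' (0.30) is chosen so that a full-contrast phantom slice scores about
#' 0.95 while a gain-0.5 slice falls well below the 0.9 gate threshold.
#' The score is monotonically non-decreasing under contrast stretching and
#' is 0 for a constant image.
#'
#' @param img grayscale matrix in \[0, 1\].
#' @param calibration contrast value mapped to score 1.
#' @return score in \[0, 1\].
#' @export
quality_score <- function(img, calibration = 0.30) {
  stopifnot_image(img)
  ot <- tryCatch(otsu_binarize(img), error = function(e) NULL)
  if (is.null(ot)) return(0)
  region <- fill_holes(ot$bin)
  if (sum(region) < 2) return(0)
  sc <- stats::sd(img[region == 1]) / calibration
  min(max(sc, 0), 1)
}

#' Contrast enhancement (surrogate)
#'
#' Sigmoid intensity remapping centred at the mean intensity of the
#' hole-filled Otsu foreground with slope `beta`, rescaled to span \[0, 1\].
#' The map is strictly monotone, so the rank order of pixel intensities is
#' preserved, and it increases the quality score of low-contrast inputs.
#'
#' @param img grayscale matrix in \[0, 1\].
#' @param beta sigmoid slope (> 0).
#' @return enhanced image in \[0, 1\].
#' @export
enhance_contrast <- function(img, beta = 4) {
  stopifnot_image(img)
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  ot <- tryCatch(otsu_binarize(img), error = function(e) NULL)
  m <- if (is.null(ot)) mean(img) else {
    region <- fill_holes(ot$bin)
    if (sum(region) >= 2) mean(img[region == 1]) else mean(img)
  }
  s <- function(x) 1 / (1 + exp(-beta * (x - m)))
  lo <- s(0); hi <- s(1)
  (s(img) - lo) / (hi - lo)
}
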