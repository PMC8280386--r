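#' @useDynLib lungseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- small internal helpers ----------------------------------------------

stopifnot_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a numeric matrix image", call. = FALSE)
}

as_binary_matrix <- function(bin) {
  stopifnot_image(bin)
  u <- unique(as.vector(bin))
  if (!all(u %in% c(0, 1)))
    stop("expected a binary (0/1) image", call. = FALSE)
  storage.mode(bin) <- "integer"
  bin
}

# shift a matrix by (dr, dc), zero-filling exposed borders
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  rs <- max(1, 1 - dr):min(H, H - dr)
  cs <- max(1, 1 - dc):min(W, W - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

# separable Gaussian blur, reflecting boundaries
gauss_blur <- function(img, sigma = 1) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(img); W <- ncol(img)
  refl <- function(i, n) { i <- abs(i - 1) + 1; i[i > n] <- 2 * n - i[i > n]; i }
  out <- matrix(0, H, W)
  for (j in seq_along(x)) out <- out + k[j] * img[refl(seq_len(H) + x[j], H), , drop = FALSE]
  res <- matrix(0, H, W)
  for (j in seq_along(x)) res <- res + k[j] * out[, refl(seq_len(W) + x[j], W), drop = FALSE]
  res
}

# bilinear resize to (h, w)
resize_bilinear <- function(img, h, w) {
  H <- nrow(img); W <- ncol(img)
  if (H == h && W == w) return(img)
  ry <- (seq_len(h) - 0.5) * H / h + 0.5
  rx <- (seq_len(w) - 0.5) * W / w + 0.5
  y0 <- pmin(pmax(floor(ry), 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(floor(rx), 1), W); x1 <- pmin(x0 + 1, W)
  fy <- pmin(pmax(ry - y0, 0), 1); fx <- pmin(pmax(rx - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    img[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    img[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
    img[y1, x1, drop = FALSE] * outer(fy, fx)
  a
}

# 3x3 square dilation / erosion of a binary image
dilate3 <- function(bin) {
  out <- matrix(0L, nrow(bin), ncol(bin))
  for (dr in -1:1) for (dc in -1:1) out <- out | shift_mat(bin, dr, dc)
  matrix(as.integer(out), nrow(bin), ncol(bin))
}

erode3 <- function(bin) {
  out <- matrix(1L, nrow(bin), ncol(bin))
  for (dr in -1:1) for (dc in -1:1) {
    s <- shift_mat(bin, dr, dc)
    out <- out & s
  }
  matrix(as.integer(out), nrow(bin), ncol(bin))
}

# ---- Otsu ------------------------------------------------------------------

#' Otsu binarization
#'
#' Chooses the threshold maximizing between-class variance over a 256-bin
#' histogram spanning the image's min--max intensity range, and binarizes with
#' foreground (value 1) the pixels brighter than the threshold.  Ties between
#' equally good cut points are broken toward the lower threshold.
#'
#' @param img numeric matrix of intensities.
#' @return list with `threshold` (on the intensity scale) and `bin`
#'   (integer 0/1 matrix, 1 = bright foreground).
#' @export
otsu_binarize <- function(img) {
  stopifnot_image(img)
  lo <- min(img); hi <- max(img)
  if (hi <= lo) stop("degenerate input: constant image has no Otsu threshold", call. = FALSE)
  nb <- 256L
  wbin <- (hi - lo) / nb
  idx <- pmin(as.integer(floor((img - lo) / wbin)), nb - 1L)  # 0..255
  counts <- tabulate(idx + 1L, nbins = nb)
  p <- counts / sum(counts)
  centers <- lo + (seq_len(nb) - 0.5) * wbin
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nb]
  # between-class variance for cut after bin k (k = 1..255 in 1-based terms)
  k <- seq_len(nb - 1L)
  denom <- w0[k] * (1 - w0[k])
  sb <- ifelse(denom > 0, (mu_t * w0[k] - mu[k])^2 / denom, -Inf)
  kstar <- which.max(sb)  # which.max takes the first (lowest) maximizer
  thr <- lo + kstar * wbin
  bin <- matrix(as.integer(idx > (kstar - 1L)), nrow(img), ncol(img))
  list(threshold = thr, bin = bin)
}

# ---- k-means clustering tree ----------------------------------------------

#' Multi-resolution k-means labeling of pixel intensities
#'
#' Partitions the pixels of a grayscale image by k-means on intensity, once
#' for every requested cluster count, producing one label image per
#' resolution.  Cluster ids are reordered so that label 1 is the darkest
#' cluster and labels increase with cluster mean intensity.
#'
#' @param img numeric matrix of intensities.
#' @param ks integer vector of cluster counts (each >= 2).
#' @param seed RNG seed making the clustering deterministic.
#' @return list of integer label matrices, one per entry of `ks`.
#' @export
clustering_tree <- function(img, ks, seed = 1L) {
  stopifnot_image(img)
  if (any(ks < 2)) stop("cluster counts must be >= 2", call. = FALSE)
  v <- as.vector(img)
  nuniq <- length(unique(v))
  out <- vector("list", length(ks))
  set.seed(as.integer(seed))
  for (i in seq_along(ks)) {
    k <- as.integer(ks[i])
    if (nuniq < k)
      stop("degenerate input: fewer distinct intensities than clusters", call. = FALSE)
    km <- stats::kmeans(v, centers = k, nstart = 10, iter.max = 100)
    ord <- order(km$centers[, 1])
    relabel <- integer(k); relabel[ord] <- seq_len(k)
    out[[i]] <- matrix(relabel[km$cluster], nrow(img), ncol(img))
  }
  out
}

# ---- connected components --------------------------------------------------

#' Connected components of a binary image
#'
#' Labels maximal connected sets of 1-pixels under 4- or 8-neighbor
#' adjacency.  Labels are assigned in raster (row-major) order of each
#' component's first pixel, making the labeling deterministic.
#'
#' @param bin binary 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return list with `labels` (integer matrix, 0 = background) and `count`.
#' @export
connected_components <- function(bin, connectivity = 8) {
  bin <- as_binary_matrix(bin)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  lab <- cpp_cc_label(bin, as.integer(connectivity))
  list(labels = lab, count = attr(lab, "count"))
}

# ---- Canny edges -----------------------------------------------------------

#' Canny edge detection
#'
#' Standard Canny chain on the input treated as a real-valued image:
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and dual-threshold hysteresis (thresholds
#' are fractions of the maximum suppressed gradient magnitude).
#'
#' @param bin binary or grayscale matrix.
#' @param sigma Gaussian smoothing standard deviation in pixels (default 1).
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude (defaults 0.1 and 0.2).
#' @return integer 0/1 matrix of edge pixels.
#' @export
canny_edges <- function(bin, sigma = 1, low = 0.1, high = 0.2) {
  stopifnot_image(bin)
  img <- gauss_blur(bin, sigma)
  gx <- shift_mat(img, 0, 1) - shift_mat(img, 0, -1) +
    0.5 * (shift_mat(img, -1, 1) - shift_mat(img, -1, -1) +
             shift_mat(img, 1, 1) - shift_mat(img, 1, -1))
  gy <- shift_mat(img, 1, 0) - shift_mat(img, -1, 0) +
    0.5 * (shift_mat(img, 1, -1) - shift_mat(img, -1, -1) +
             shift_mat(img, 1, 1) - shift_mat(img, -1, 1))
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx == 0) return(matrix(0L, nrow(bin), ncol(bin)))
  # quantize direction into 4 sectors and suppress non-maxima
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  n1 <- matrix(0, nrow(mag), ncol(mag)); n2 <- n1
  dirs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))  # E, SE, S, SW
  for (s in 0:3) {
    d <- dirs[[s + 1]]
    sel <- sector == s
    a <- shift_mat(mag, d[1], d[2]); b <- shift_mat(mag, -d[1], -d[2])
    n1[sel] <- a[sel]; n2[sel] <- b[sel]
  }
  keep <- (mag >= n1) & (mag >= n2)
  nms <- ifelse(keep, mag, 0)
  strong <- nms >= high * mx
  weak <- nms >= low * mx
  if (!any(strong)) return(matrix(0L, nrow(bin), ncol(bin)))
  lab <- cpp_cc_label(matrix(as.integer(weak), nrow(bin), ncol(bin)), 8L)
  good <- unique(lab[strong])
  good <- good[good > 0]
  matrix(as.integer(lab %in% good), nrow(bin), ncol(bin))
}

# ---- hole filling ----------------------------------------------------------

#' Fill enclosed holes of a binary image
#'
#' A hole is a background component not connected to the image border
#' (4-connectivity on the background, the standard complement of
#' 8-connectivity on the foreground).  The output is the input plus all such
#' components.
#'
#' @param bin binary 0/1 matrix.
#' @return integer 0/1 matrix with holes filled.
#' @export
fill_holes <- function(bin) {
  bin <- as_binary_matrix(bin)
  bg <- 1L - bin
  lab <- cpp_cc_label(bg, 4L)
  H <- nrow(bin); W <- ncol(bin)
  border <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  border <- border[border > 0]
  hole <- lab > 0 & !(lab %in% border)
  matrix(as.integer(bin | hole), H, W)
}

# ---- candidate lung region -------------------------------------------------

#' Extract the candidate lung region
#'
#' The candidate lung region consists of the dark cavities enclosed by the
#' binarized body foreground: pixels that are background in `body` but
#' foreground after hole filling.  Components smaller than a minimum area
#' fraction of the image are suppressed as specks.
#'
#' @param img grayscale image the body was binarized from (kept for the
#'   interface contract; the candidate is defined by `body` alone).
#' @param body binary body/foreground image (1 = bright body).
#' @param min_area_frac minimum component area as a fraction of the image
#'   area (default 0.001).
#' @return integer 0/1 matrix of candidate lung pixels.
#' @export
candidate_lung_region <- function(img, body, min_area_frac = 0.001) {
  body <- as_binary_matrix(body)
  holes <- fill_holes(body) - body
  if (!any(holes > 0)) return(matrix(0L, nrow(body), ncol(body)))
  cc <- connected_components(holes, 8)
  min_area <- min_area_frac * length(body)
  sizes <- tabulate(cc$labels[cc$labels > 0], nbins = cc$count)
  keep <- which(sizes >= min_area)
  matrix(as.integer(cc$labels %in% keep), nrow(body), ncol(body))
}

# ---- contour quality -------------------------------------------------------

#' Contour-quality statistic of a candidate region
#'
#' Computes `A1`, the Canny edge-pixel count of the region, `A2`, the pixel
#' count of the hole-filled region, and their ratio `tau2 = A2 / A1`.
#' Correctly extracted lung regions have completely filled areas bounded by
#' smooth closed contours, so `tau2` grows with contour quality (for an ideal
#' disk it grows linearly with the radius).  An empty edge image yields
#' `tau2 = 0`, the worst quality, which always routes a region to refinement.
#'
#' @param region binary 0/1 matrix.
#' @return object of class `contour_quality`: list with `A1`, `A2`, `tau2`.
#' @export
contour_quality <- function(region) {
  region <- as_binary_matrix(region)
  A1 <- sum(canny_edges(region))
  A2 <- sum(fill_holes(region))
  tau2 <- if (A1 > 0) A2 / A1 else 0
  structure(list(A1 = A1, A2 = A2, tau2 = tau2), class = "contour_quality")
}

#' @export
print.contour_quality <- function(x, ...) {
  cat(sprintf("contour quality: A1 = %d edge px, A2 = %d filled px, tau2 = %.3f\n",
              x$A1, x$A2, x$tau2))
  invisible(x)
}

# ---- Dice ------------------------------------------------------------------

#' Dice similarity coefficient
#'
#' `2 |X intersect Y| / (|X| + |Y|)` between two binary masks of identical
#' dimensions.  Two empty masks are defined to agree perfectly (score 1).
#'
#' @param X,Y binary 0/1 matrices of identical dimensions.
#' @return numeric Dice score in \[0, 1\].
#' @export
dice_score <- function(X, Y) {
  X <- as_binary_matrix(X); Y <- as_binary_matrix(Y)
  if (!identical(dim(X), dim(Y))) stop("mask dimensions differ", call. = FALSE)
  sx <- sum(X); sy <- sum(Y)
  if (sx + sy == 0) return(1)
  2 * sum(X & Y) / (sx + sy)
}
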