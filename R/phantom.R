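# Synthetic thorax phantom: axial CT-like slices with exact ground truth.
#
# A slice is rendered from nominal tissue intensity levels on a normalized
# [0,1] scale: background 0.05, body 0.75, lung fields 0.15, pathology
# patches 0.65, table artifact 0.55.  The levels are chosen so that Otsu
# thresholding separates the bright body from dark air, as in real CT.

PHANTOM_LEVELS <- c(background = 0.05, body = 0.75, lung = 0.15,
                    pathology = 0.65, table = 0.55)

#' Phantom slice parameters
#'
#' Parameter set for one synthetic thorax slice.  Geometry is given in
#' fractions of the image side: ellipses as `c(center_row, center_col,
#' semi_axis_row, semi_axis_col)`.
#'
#' @param image_size pixels per side (square, >= 64).
#' @param lung_present logical; if `FALSE` the slice carries no lung fields
#'   and an empty ground-truth mask (a superior/inferior slice).
#' @param pathology_severity fraction in \[0, 1\] of lung-contour pixels
#'   disrupted by bright boundary patches (ground-glass/fibrosis-like).
#' @param noise_sigma additive Gaussian noise standard deviation in
#'   normalized intensity units.
#' @param contrast_gain multiplicative contrast factor about mid-gray 0.5;
#'   values below 1 flatten the slice (low-dose-like contrast loss).
#' @param body_ellipse,lung_ellipses body geometry and a list of lung
#'   geometries, in side fractions; `NULL` for anatomical defaults.
#' @param table_artifact logical; render a bright table-like band below the
#'   body.
#' @param gas_pockets number of small dark distractor pockets (bowel-gas
#'   like) rendered inside the body but outside the lungs.
#' @param seed integer RNG seed; identical parameters and seed give a
#'   bit-identical slice.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 128, lung_present = TRUE,
                           pathology_severity = 0, noise_sigma = 0.01,
                           contrast_gain = 1, body_ellipse = NULL,
                           lung_ellipses = NULL, table_artifact = TRUE,
                           gas_pockets = 0, seed = 1L) {
  if (image_size < 64) stop("invalid parameter: image_size must be >= 64", call. = FALSE)
  if (pathology_severity < 0 || pathology_severity > 1)
    stop("invalid parameter: pathology_severity must be in [0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("invalid parameter: noise_sigma must be >= 0", call. = FALSE)
  if (contrast_gain <= 0) stop("invalid parameter: contrast_gain must be > 0", call. = FALSE)
  if (is.null(body_ellipse)) body_ellipse <- c(0.52, 0.50, 0.36, 0.42)
  if (is.null(lung_ellipses))
    lung_ellipses <- list(c(0.50, 0.33, 0.22, 0.13), c(0.50, 0.67, 0.22, 0.13))
  check_ellipse <- function(e, what) {
    if (length(e) != 4 || any(!is.finite(e)))
      stop("invalid parameter: ", what, " must be 4 finite numbers", call. = FALSE)
    if (e[1] - e[3] < 0.02 || e[1] + e[3] > 0.98 ||
        e[2] - e[4] < 0.02 || e[2] + e[4] > 0.98)
      stop("invalid parameter: ", what, " does not fit inside the image", call. = FALSE)
  }
  check_ellipse(body_ellipse, "body_ellipse")
  for (e in lung_ellipses) check_ellipse(e, "lung ellipse")
  structure(list(image_size = as.integer(image_size), lung_present = lung_present,
                 pathology_severity = pathology_severity, noise_sigma = noise_sigma,
                 contrast_gain = contrast_gain, body_ellipse = body_ellipse,
                 lung_ellipses = lung_ellipses, table_artifact = table_artifact,
                 gas_pockets = as.integer(gas_pockets), seed = as.integer(seed)),
            class = "phantom_params")
}

# inside-ellipse indicator with optional low-frequency boundary perturbation
ellipse_mask <- function(n, e, wobble = NULL) {
  cy <- e[1] * n; cx <- e[2] * n; ay <- e[3] * n; ax <- e[4] * n
  dy <- (seq_len(n) - cy) / ay
  dx <- (seq_len(n) - cx) / ax
  DY <- matrix(dy, n, n); DX <- matrix(dx, n, n, byrow = TRUE)
  rho <- sqrt(DY^2 + DX^2)
  if (is.null(wobble)) return(rho <= 1)
  th <- atan2(DY, DX)
  lim <- 1 + wobble$a1 * sin(2 * th + wobble$p1) + wobble$a2 * sin(3 * th + wobble$p2)
  rho <= lim
}

#' Generate one synthetic thorax slice
#'
#' Renders a slice from [phantom_params()]: dark background, bright body
#' ellipse, two dark lung fields with smooth (jittered and low-frequency
#' perturbed) contours, an optional table artifact and optional dark gas
#' pockets.  If `pathology_severity > 0`, bright patches overwrite the
#' requested fraction of lung-boundary pixels so the lung/body intensity
#' edge is locally erased; the ground-truth mask is unaffected.  Noise and
#' the contrast factor are applied last, followed by clipping to \[0, 1\].
#'
#' @param params a [phantom_params()] object.
#' @return object of class `lungseg_slice`: list with `image` (numeric
#'   matrix in \[0,1\]), `mask` (integer 0/1 ground-truth lung mask),
#'   `contains_lung` and `params`.
#' @export
make_thorax_slice <- function(params) {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  n <- params$image_size
  set.seed(params$seed)
  lv <- PHANTOM_LEVELS
  jit <- function(e, s = 0.05) {
    e + c(stats::runif(2, -0.015, 0.015), e[3:4] * stats::runif(2, -s, s))
  }
  body_e <- jit(params$body_ellipse, 0.04)
  body <- ellipse_mask(n, body_e)
  img <- matrix(lv["background"], n, n)
  img[body] <- lv["body"]

  if (params$table_artifact) {
    r0 <- round(0.93 * n); r1 <- min(n, r0 + max(2L, round(0.015 * n)))
    c0 <- round(0.20 * n); c1 <- round(0.80 * n)
    tab <- matrix(FALSE, n, n); tab[r0:r1, c0:c1] <- TRUE
    tab <- tab & !body
    img[tab] <- lv["table"]
  }

  mask <- matrix(FALSE, n, n)
  if (params$lung_present) {
    for (e in params$lung_ellipses) {
      w <- list(a1 = stats::runif(1, 0.02, 0.05), p1 = stats::runif(1, 0, 2 * pi),
                a2 = stats::runif(1, 0.01, 0.04), p2 = stats::runif(1, 0, 2 * pi))
      mask <- mask | (ellipse_mask(n, jit(e, 0.06), w) & body)
    }
    img[mask] <- lv["lung"]
  }

  if (params$lung_present && params$pathology_severity > 0) {
    maskI <- matrix(as.integer(mask), n, n)
    boundary <- which(maskI == 1 & dilate3(1L - maskI) == 1L, arr.ind = TRUE)
    nb <- nrow(boundary)
    target <- ceiling(params$pathology_severity * nb)
    disrupted <- rep(FALSE, nb)
    ord <- sample.int(nb)
    rad_lo <- 0.03 * n; rad_hi <- 0.06 * n
    for (i in ord) {
      if (sum(disrupted) >= target) break
      if (disrupted[i]) next
      ctr <- boundary[i, ]
      rad <- stats::runif(1, rad_lo, rad_hi)
      dr <- matrix(seq_len(n) - ctr[1], n, n)
      dc <- matrix(seq_len(n) - ctr[2], n, n, byrow = TRUE)
      blob <- (dr^2 + dc^2) <= rad^2
      img[blob & body] <- lv["pathology"]
      d2 <- (boundary[, 1] - ctr[1])^2 + (boundary[, 2] - ctr[2])^2
      disrupted <- disrupted | (d2 <= rad^2)
    }
  }

  if (params$gas_pockets > 0) {
    placed <- 0L; tries <- 0L
    while (placed < params$gas_pockets && tries < 100L) {
      tries <- tries + 1L
      ctr <- round(c(stats::runif(1, (body_e[1] - 0.7 * body_e[3]) * n,
                                  (body_e[1] + 0.7 * body_e[3]) * n),
                     stats::runif(1, (body_e[2] - 0.7 * body_e[4]) * n,
                                  (body_e[2] + 0.7 * body_e[4]) * n)))
      rad <- stats::runif(1, 0.025, 0.045) * n
      dr <- matrix(seq_len(n) - ctr[1], n, n)
      dc <- matrix(seq_len(n) - ctr[2], n, n, byrow = TRUE)
      blob <- (dr^2 + dc^2) <= rad^2
      near <- (dr^2 + dc^2) <= (rad + 3)^2
      if (!all(body[blob])) next
      if (params$lung_present && any(mask[near])) next
      img[blob] <- lv["lung"]
      placed <- placed + 1L
    }
  }

  if (params$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, params$noise_sigma), n, n)
  img <- 0.5 + params$contrast_gain * (img - 0.5)
  img <- pmin(pmax(img, 0), 1)

  structure(list(image = img,
                 mask = matrix(as.integer(params$lung_present & mask), n, n),
                 contains_lung = isTRUE(params$lung_present),
                 params = params),
            class = "lungseg_slice")
}

#' @export
print.lungseg_slice <- function(x, ...) {
  cat(sprintf("synthetic thorax slice %dx%d: %s, severity %.2f, noise %.3f, gain %.2f\n",
              nrow(x$image), ncol(x$image),
              if (x$contains_lung) sprintf("lung (%d mask px)", sum(x$mask)) else "no lung",
              x$params$pathology_severity, x$params$noise_sigma, x$params$contrast_gain))
  invisible(x)
}

#' Generate a seeded phantom dataset
#'
#' Draws `n` phantom slices with approximately `lung_fraction * n` of them
#' containing lung fields, pathology severity uniform over
#' `severity_range`, a mixture of contrast gains, and occasional dark
#' distractor pockets.  Split tags (train/val/test) are assigned
#' deterministically from the seed, stratified by lung presence.
#'
#' @param n number of slices (>= 1).
#' @param lung_fraction fraction of slices containing lungs.
#' @param severity_range length-2 interval for pathology severity.
#' @param image_size pixels per side.
#' @param noise_sigma additive noise level for every slice.
#' @param gain_levels,gain_prob contrast gains sampled per slice and their
#'   probabilities; the default includes a low-contrast level that
#'   exercises the quality-enhancement gate.
#' @param pocket_rate expected number of gas pockets per slice (sampled as
#'   Poisson, capped at 3).
#' @param split named fractions for the train/val/test tags (must sum to 1).
#' @param seed integer master seed.
#' @return list with `slices` (list of `lungseg_slice`) and `manifest`
#'   (data frame of per-slice parameters and split tags).
#' @export
make_dataset <- function(n, lung_fraction = 0.8, severity_range = c(0, 0.3),
                         image_size = 128, noise_sigma = 0.01,
                         gain_levels = c(1, 0.5), gain_prob = c(0.75, 0.25),
                         pocket_rate = 0.3,
                         split = c(train = 0.7, val = 0.15, test = 0.15),
                         seed = 1L) {
  if (n < 1) stop("invalid parameter: n must be >= 1", call. = FALSE)
  if (lung_fraction < 0 || lung_fraction > 1)
    stop("invalid parameter: lung_fraction must be in [0, 1]", call. = FALSE)
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1", call. = FALSE)
  set.seed(as.integer(seed))
  lung <- stats::runif(n) < lung_fraction
  sev <- stats::runif(n, severity_range[1], severity_range[2])
  sev[!lung] <- 0
  gain <- sample(gain_levels, n, replace = TRUE, prob = gain_prob)
  pockets <- pmin(stats::rpois(n, pocket_rate), 3L)
  seeds <- sample.int(.Machine$integer.max - 1L, n)

  # deterministic stratified split tags
  tags <- character(n)
  for (grp in list(which(lung), which(!lung))) {
    m <- length(grp)
    if (m == 0) next
    counts <- floor(split * m)
    rem <- m - sum(counts)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
    tag <- rep(names(split), counts)
    tags[grp] <- tag[sample.int(m)]
  }

  slices <- vector("list", n)
  for (i in seq_len(n)) {
    p <- phantom_params(image_size = image_size, lung_present = lung[i],
                        pathology_severity = sev[i], noise_sigma = noise_sigma,
                        contrast_gain = gain[i], gas_pockets = pockets[i],
                        seed = seeds[i])
    slices[[i]] <- make_thorax_slice(p)
  }
  manifest <- data.frame(id = seq_len(n), seed = seeds, contains_lung = lung,
                         severity = sev, noise_sigma = noise_sigma,
                         contrast_gain = gain, gas_pockets = pockets,
                         split = tags, stringsAsFactors = FALSE)
  list(slices = slices, manifest = manifest)
}
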