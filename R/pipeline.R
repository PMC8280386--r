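# Three-stage orchestration: pre-processing (slice gate + quality gate),
# processing (U-net binarization + candidate-lung-region extraction) and
# post-processing (contour-quality-gated refinement, hole filling,
# component-level false-positive filtering).

#' Pipeline configuration
#'
#' Bundles the trained models, the system mode and the gate parameters.
#' Modes: `three_stage` is the full system; `without_cnns` removes both
#' classifier networks (slice gate and component filter) while keeping the
#' U-nets; `without_enhancement` removes only the quality evaluation and
#' contrast enhancement.
#'
#' @param models named list with entries `cnn1`, `unet1`, `unet2`, `cnn2`
#'   (entries not required by the mode may be `NULL`).
#' @param mode one of `"three_stage"`, `"without_cnns"`,
#'   `"without_enhancement"`.
#' @param tau2_threshold contour-quality threshold routing candidates to
#'   refinement when `tau2` falls below it (default 12).
#' @param gate a [quality_gate()].
#' @param min_area_frac minimum candidate-component area as a fraction of
#'   the image (default 0.001).
#' @param unet1_input `"auto"` feeds the binarizer U-net the Otsu binary
#'   image when it was trained on binary inputs (configurations 1--3) and
#'   the grayscale slice otherwise; `"binary"`/`"gray"` force either mode.
#' @param refine logical; disable to skip contour refinement entirely
#'   (used to measure refinement efficacy).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(models, mode = c("three_stage", "without_cnns",
                                             "without_enhancement"),
                            tau2_threshold = 12, gate = quality_gate(),
                            min_area_frac = 0.001,
                            unet1_input = c("auto", "binary", "gray"),
                            refine = TRUE) {
  mode <- match.arg(mode)
  unet1_input <- match.arg(unet1_input)
  if (tau2_threshold <= 0) stop("tau2_threshold must be > 0", call. = FALSE)
  if (is.null(models$unet1)) stop("configuration error: unet1 model is required", call. = FALSE)
  if (mode != "without_cnns") {
    if (is.null(models$cnn1)) stop("configuration error: cnn1 required in mode ", mode, call. = FALSE)
    if (is.null(models$cnn2)) stop("configuration error: cnn2 required in mode ", mode, call. = FALSE)
  }
  if (refine && is.null(models$unet2))
    stop("configuration error: unet2 required when refinement is enabled", call. = FALSE)
  structure(list(models = models, mode = mode, tau2_threshold = tau2_threshold,
                 gate = gate, min_area_frac = min_area_frac,
                 unet1_input = unet1_input, refine = refine),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("lung segmentation pipeline: mode %s, tau2 threshold %g, tau1 %g%s\n",
              x$mode, x$tau2_threshold, x$gate$tau1,
              if (x$refine) "" else ", refinement disabled"))
  invisible(x)
}

# cached model call: cache is an environment, key identifies (model, input)
cached <- function(cache, key, expr) {
  if (is.null(cache)) return(expr)
  if (!is.null(cache[[key]])) return(cache[[key]])
  val <- expr
  cache[[key]] <- val
  val
}

resolve_unet1_input <- function(cfg) {
  if (cfg$unet1_input != "auto") return(cfg$unet1_input)
  cid <- cfg$models$unet1$config_id
  if (!is.null(cid) && cid %in% 1:3) "binary" else "gray"
}

#' Pre-processing stage
#'
#' Otsu-binarizes the slice and feeds the binary image to the slice-gate
#' classifier: a `none_lung` prediction short-circuits the pipeline with an
#' all-zero mask.  For lung slices the no-reference quality score is
#' evaluated and, when it falls below the gate threshold, the slice is
#' contrast-enhanced before moving on.  The `without_cnns` mode always
#' proceeds; the `without_enhancement` mode skips the quality gate.
#'
#' @param img grayscale slice in \[0, 1\].
#' @param cfg a [pipeline_config()].
#' @param .cache,.id internal prediction cache (used by [evaluate_pipeline()]).
#' @return list with `proceed`, `img` (possibly enhanced), and `trace`.
#' @export
preprocess_slice <- function(img, cfg, .cache = NULL, .id = NULL) {
  bim <- otsu_binarize(img)$bin
  trace <- list(BIM = bim)
  if (cfg$mode != "without_cnns") {
    m <- cfg$models$cnn1
    inp <- resize_for_model(bim, m$spec$input_size)
    pred <- cached(.cache, paste("cnn1", m$uid, .id), predict_class(m, inp))
    trace$cnn1 <- pred
    if (pred$class == "none_lung")
      return(list(proceed = FALSE, img = img, trace = trace))
  } else trace$cnn1 <- NULL
  enhanced <- FALSE
  if (cfg$mode != "without_enhancement") {
    sc <- cfg$gate$score_fun(img)
    trace$quality_score <- sc
    if (sc < cfg$gate$tau1) {
      img <- cfg$gate$enhance_fun(img, cfg$gate$beta)
      enhanced <- TRUE
    }
  }
  trace$enhanced <- enhanced
  list(proceed = TRUE, img = img, trace = trace)
}

#' Processing stage
#'
#' The binarizer U-net converts the slice to a label image whose bright
#' class is the body foreground (`TCB`); the candidate lung region (`TCR`)
#' is then extracted as the dark cavities enclosed by that foreground.
#'
#' @param img grayscale slice (possibly enhanced) in \[0, 1\].
#' @param cfg a [pipeline_config()].
#' @param .cache,.id internal prediction cache.
#' @return list with `candidate` and `trace` (`TCB`, `TCR`).
#' @export
process_slice <- function(img, cfg, .cache = NULL, .id = NULL) {
  m <- cfg$models$unet1
  mode_in <- resolve_unet1_input(cfg)
  x <- if (mode_in == "binary") otsu_binarize(img)$bin + 0 else img
  lab <- cached(.cache, paste("unet1", m$uid, .id, mode_in), predict_mask(m, x))
  tcb <- mask_binary_view(lab, x)
  tcr <- candidate_lung_region(img, tcb, cfg$min_area_frac)
  list(candidate = tcr, trace = list(TCB = tcb, TCR = tcr))
}

#' Post-processing stage
#'
#' Computes the contour-quality statistic of the candidate region; when
#' `tau2` falls below the threshold the refinement U-net predicts a closed
#' contour which is laid over the candidate and morphologically closed
#' (dilate, hole-fill, erode) so 1--2 px contour gaps seal without adding an
#' outward rim.  The filled region is split into
#' connected components, each component is classified by the component
#' filter (skipped in `without_cnns` mode), and the surviving components
#' form the segmented mask.
#'
#' @param candidate binary candidate lung region.
#' @param cfg a [pipeline_config()].
#' @param .cache,.id internal prediction cache.
#' @return list with `mask` and `trace` (`tau2`, `refined`, `TCM`,
#'   component decisions).
#' @export
postprocess_slice <- function(candidate, cfg, .cache = NULL, .id = NULL) {
  cq <- contour_quality(candidate)
  trace <- list(tau2 = cq$tau2, contour_quality = cq)
  refined <- cfg$refine && cq$tau2 < cfg$tau2_threshold
  if (refined) {
    m <- cfg$models$unet2
    lab <- cached(.cache, paste("unet2", m$uid, .id), predict_mask(m, candidate + 0))
    tcm <- matrix(as.integer(lab == 1L), nrow(candidate), ncol(candidate))
    trace$TCM <- tcm
    # overlay the predicted contour on the candidate, close hairline gaps by
    # dilation, fill, then erode back so the closing adds no outward rim
    overlay <- matrix(as.integer(tcm | candidate), nrow(candidate), ncol(candidate))
    region <- erode3(fill_holes(dilate3(overlay)))
  } else {
    region <- fill_holes(candidate)
  }
  trace$refined <- refined
  cc <- connected_components(region, 8)
  kept <- matrix(0L, nrow(candidate), ncol(candidate))
  n_kept <- 0L; n_dropped <- 0L
  for (k in seq_len(cc$count)) {
    comp <- matrix(as.integer(cc$labels == k), nrow(candidate), ncol(candidate))
    keep <- TRUE
    if (cfg$mode != "without_cnns") {
      m2 <- cfg$models$cnn2
      inp <- resize_for_model(comp, m2$spec$input_size)
      pred <- cached(.cache, paste("cnn2", m2$uid, .id, k, refined),
                     predict_class(m2, inp))
      keep <- pred$class == "lung"
    }
    if (keep) { kept <- kept | comp; n_kept <- n_kept + 1L }
    else n_dropped <- n_dropped + 1L
  }
  trace$components_kept <- n_kept
  trace$components_dropped <- n_dropped
  list(mask = matrix(as.integer(kept), nrow(candidate), ncol(candidate)),
       trace = trace)
}

#' Segment one CT slice
#'
#' Runs the full three-stage composition on a grayscale slice (or a
#' `lungseg_slice`), returning the segmented mask together with a trace of
#' every intermediate image and gate decision.  A `none_lung` slice-gate
#' prediction short-circuits to an all-zero mask with no downstream
#' computation.
#'
#' @param img numeric matrix in \[0, 1\], or a `lungseg_slice`.
#' @param cfg a [pipeline_config()].
#' @param .cache,.id internal prediction cache.
#' @return object of class `lungseg_result`: list with `mask` (0/1 matrix)
#'   and `trace`.
#' @export
segment_slice <- function(img, cfg, .cache = NULL, .id = NULL) {
  if (inherits(img, "lungseg_slice")) img <- img$image
  stopifnot_image(img)
  pre <- preprocess_slice(img, cfg, .cache, .id)
  trace <- pre$trace
  if (!pre$proceed) {
    trace$contains_lung <- FALSE
    return(structure(list(mask = matrix(0L, nrow(img), ncol(img)), trace = trace),
                     class = "lungseg_result"))
  }
  trace$contains_lung <- TRUE
  enh_tag <- if (isTRUE(trace$enhanced)) "enh" else "raw"
  pr <- process_slice(pre$img, cfg, .cache, paste(.id, enh_tag))
  trace <- c(trace, pr$trace)
  po <- postprocess_slice(pr$candidate, cfg, .cache, paste(.id, enh_tag))
  trace <- c(trace, po$trace)
  structure(list(mask = po$mask, trace = trace), class = "lungseg_result")
}

#' @export
print.lungseg_result <- function(x, ...) {
  t <- x$trace
  if (!isTRUE(t$contains_lung)) {
    cat("segmentation result: slice gated out as none_lung (zero mask)\n")
    return(invisible(x))
  }
  cat(sprintf("segmentation result: %d mask px; tau2 = %.2f (%s); %d component(s) kept, %d dropped%s\n",
              sum(x$mask), t$tau2,
              if (isTRUE(t$refined)) "refined" else "not refined",
              t$components_kept, t$components_dropped,
              if (isTRUE(t$enhanced)) "; contrast enhanced" else ""))
  invisible(x)
}

#' @export
plot.lungseg_result <- function(x, ...) {
  t <- x$trace
  panels <- Filter(Negate(is.null),
                   list(`Otsu binary` = t$BIM, `U-net body` = t$TCB,
                        `candidate` = t$TCR, `refined contour` = t$TCM,
                        `segmented` = x$mask))
  op <- graphics::par(mfrow = c(1, max(1, length(panels))), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (nm in names(panels)) {
    m <- panels[[nm]]
    graphics::image(t(m[nrow(m):1, ]), col = grDevices::gray.colors(64, 0, 1),
                    axes = FALSE, main = nm)
  }
  invisible(x)
}

#' Evaluate pipeline configurations on a slice set
#'
#' Segments every slice under every configuration and reports the mean Dice
#' score against the ground-truth masks, overall and over lung slices only.
#' Model predictions are cached across configurations that share models, so
#' ablation grids do not recompute identical forward passes.  Slices
#' without ground truth are skipped with a warning.
#'
#' @param slices list of `lungseg_slice` records.
#' @param cfgs list of [pipeline_config()] objects (optionally named).
#' @return data frame with one row per configuration (`mode`, `config_id`,
#'   `mean_dice`, `mean_dice_lung`, `n`); per-slice scores are attached as
#'   attribute `"per_slice"`.
#' @export
evaluate_pipeline <- function(slices, cfgs) {
  if (inherits(cfgs, "pipeline_config")) cfgs <- list(cfgs)
  has_gt <- vapply(slices, function(s) is.matrix(s$mask), logical(1))
  if (any(!has_gt)) {
    warning(sum(!has_gt), " slice(s) without ground truth skipped")
    slices <- slices[has_gt]
  }
  cache <- new.env(parent = emptyenv())
  per <- matrix(NA_real_, length(slices), length(cfgs))
  lung <- vapply(slices, function(s) isTRUE(s$contains_lung), logical(1))
  for (j in seq_along(cfgs)) {
    for (i in seq_along(slices)) {
      res <- segment_slice(slices[[i]], cfgs[[j]], .cache = cache, .id = i)
      per[i, j] <- dice_score(res$mask, slices[[i]]$mask)
    }
  }
  out <- data.frame(
    config = if (is.null(names(cfgs))) seq_along(cfgs) else names(cfgs),
    mode = vapply(cfgs, function(cf) cf$mode, character(1)),
    config_id = vapply(cfgs, function(cf) {
      cid <- cf$models$unet1$config_id
      if (is.null(cid)) NA_integer_ else as.integer(cid)
    }, integer(1)),
    mean_dice = colMeans(per),
    mean_dice_lung = apply(per, 2, function(v) mean(v[lung])),
    n = length(slices),
    stringsAsFactors = FALSE)
  attr(out, "per_slice") <- per
  out
}
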