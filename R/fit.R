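#' Fit the three-stage lung segmentation system
#'
#' Headline fitting function: builds the four training sets from a labeled
#' slice collection and trains the slice-gate classifier, the binarizer
#' U-net (one of the five training-data configurations), the contour
#' refinement U-net and the component-filter classifier.  The returned
#' system segments new slices through [predict.lungseg_system()] in any of
#' the three system modes.
#'
#' @param data result of [make_dataset()], or a plain list of
#'   `lungseg_slice` records (then all slices are used for training).
#' @param config_id training-data configuration for the binarizer U-net
#'   (1..5; default 2, the Otsu-binary identity configuration).
#' @param train_cfg a [train_config()]; its seed drives all four trainings
#'   (each model gets a distinct derived seed).
#' @param iters named iteration caps per network, the desk-scale training
#'   budget.
#' @param unet_batch minibatch size for the U-nets (the classifier keeps
#'   the configured minibatch; full frames are memory-heavier, so the
#'   U-nets train on smaller batches by default).
#' @param classifier_size input side for both classifiers.
#' @param tau2_threshold,gate pipeline gate parameters stored with the
#'   system.
#' @param verbose print training progress.
#' @return object of class `lungseg_system`.
#' @export
lungseg_fit <- function(data, config_id = 2, train_cfg = train_config(),
                        iters = c(cnn1 = 120, unet1 = 80, unet2 = 300, cnn2 = 120),
                        unet_batch = 4, classifier_size = 64, tau2_threshold = 12,
                        gate = quality_gate(), verbose = FALSE) {
  slices <- if (is.list(data) && !is.null(data$slices)) {
    tr <- data$manifest$split == "train"
    data$slices[tr]
  } else data
  if (length(slices) < 4) stop("need at least a handful of training slices", call. = FALSE)
  size <- nrow(slices[[1]]$image)

  cfg_for <- function(what, seed_off) {
    cfg <- train_cfg
    cfg$seed <- train_cfg$seed + seed_off
    cfg$max_iterations <- min(cfg$max_iterations, unname(iters[what]))
    if (what %in% c("unet1", "unet2"))
      cfg$minibatch_size <- min(cfg$minibatch_size, as.integer(unet_batch))
    cfg
  }

  if (verbose) message("building training sets ...")
  set_cnn1 <- build_cnn1_set(slices)
  set_unet1 <- build_unet1_set(slices, config_id, seed = train_cfg$seed)
  set_unet2 <- build_unet2_set(slices)
  set_cnn2 <- build_cnn2_set(slices, seed = train_cfg$seed)

  if (verbose) message("training slice-gate classifier ...")
  cnn1 <- train_classifier(set_cnn1, classifier_spec(classifier_size),
                           cfg_for("cnn1", 11L), verbose = verbose)
  if (verbose) message("training binarizer U-net (configuration ", config_id, ") ...")
  unet1 <- train_unet(set_unet1,
                      unet_spec(classes = set_unet1$label_arity, input_size = size),
                      cfg_for("unet1", 22L), verbose = verbose)
  if (verbose) message("training contour-refinement U-net ...")
  unet2 <- train_unet(set_unet2, unet_spec(classes = 2, input_size = size),
                      cfg_for("unet2", 33L), verbose = verbose)
  if (verbose) message("training component-filter classifier ...")
  cnn2 <- train_classifier(set_cnn2, classifier_spec(classifier_size),
                           cfg_for("cnn2", 44L), verbose = verbose)

  structure(list(models = list(cnn1 = cnn1, unet1 = unet1, unet2 = unet2, cnn2 = cnn2),
                 config_id = config_id, image_size = size,
                 tau2_threshold = tau2_threshold, gate = gate,
                 train_cfg = train_cfg, n_train = length(slices)),
            class = "lungseg_system")
}

#' Pipeline configuration from a fitted system
#'
#' @param system a `lungseg_system`.
#' @param mode system mode (see [pipeline_config()]).
#' @param ... further arguments passed to [pipeline_config()].
#' @return a [pipeline_config()].
#' @export
system_pipeline <- function(system, mode = "three_stage", ...) {
  stopifnot(inherits(system, "lungseg_system"))
  args <- list(models = system$models, mode = mode,
               tau2_threshold = system$tau2_threshold, gate = system$gate)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(pipeline_config, args)
}

#' @export
print.lungseg_system <- function(x, ...) {
  cat(sprintf("three-stage lung segmentation system (trained on %d slices, %dx%d)\n",
              x$n_train, x$image_size, x$image_size))
  cat(sprintf("  binarizer U-net: training-data configuration %d\n", x$config_id))
  cat(sprintf("  gates: tau1 = %g (quality), tau2 threshold = %g (contour)\n",
              x$gate$tau1, x$tau2_threshold))
  invisible(x)
}

#' @export
summary.lungseg_system <- function(object, ...) {
  cat(sprintf("three-stage lung segmentation system\n"))
  for (nm in names(object$models)) {
    cat(sprintf("-- %s: ", nm)); print(object$models[[nm]])
  }
  invisible(object)
}

#' Segment slices with a fitted system
#'
#' @param object a `lungseg_system`.
#' @param newdata a grayscale matrix, a `lungseg_slice`, or a list of
#'   either.
#' @param mode system mode (see [pipeline_config()]).
#' @param ... further arguments passed to [pipeline_config()].
#' @return a `lungseg_result`, or a list of them for list input.
#' @export
predict.lungseg_system <- function(object, newdata, mode = "three_stage", ...) {
  cfg <- system_pipeline(object, mode, ...)
  if (is.matrix(newdata) || inherits(newdata, "lungseg_slice"))
    return(segment_slice(newdata, cfg))
  lapply(newdata, segment_slice, cfg = cfg)
}

#' @export
plot.lungseg_system <- function(x, slice, mode = "three_stage", ...) {
  res <- predict(x, slice, mode = mode)
  plot(res)
  invisible(res)
}
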