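# Model specifications, training and inference for the two classifier
# networks (slice gate, component filter) and the two U-nets (binarizer,
# contour refiner).

.lungseg_state <- new.env(parent = emptyenv())
.lungseg_state$uid <- 0L

next_uid <- function() {
  .lungseg_state$uid <- .lungseg_state$uid + 1L
  sprintf("model%03d", .lungseg_state$uid)
}

#' Classifier architecture specification
#'
#' Three convolution stages with 8, 16 and 32 filters of size 3x3, each
#' stage stacked as convolution, rectifier, batch normalization and 2x2 max
#' pooling, followed by a fully connected layer with softmax over two
#' classes (`lung` / `none_lung`).
#'
#' @param input_size side length the single-channel input is resized to
#'   (must be divisible by 8; default 64).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(input_size = 64) {
  if (input_size %% 8 != 0) stop("input_size must be divisible by 8", call. = FALSE)
  structure(list(filters = c(8L, 16L, 32L), kernel = 3L, classes = 2L,
                 input_size = as.integer(input_size)),
            class = "classifier_spec")
}

#' U-net architecture specification
#'
#' Encoder of two 3x3 convolution layers (64 filters each) with rectifiers
#' and max pooling for a total down-sampling factor of 4; decoder of two
#' 3x3 transposed-convolution layers (64 filters each) with rectifiers for
#' a total up-sampling factor of 4; per-pixel class scores as output head.
#' Convolutions are unpadded ("valid") and their results live in a
#' fixed-size frame with a zeroed border, so the output is spatially aligned
#' with the input pixel by pixel.
#'
#' @param classes number of per-pixel classes (2 or 3).
#' @param input_size side length of the (square) training frames; inputs of
#'   other sizes are resized at prediction time.  Must be divisible by 4.
#' @return object of class `unet_spec`.
#' @export
unet_spec <- function(classes = 2, input_size = 128) {
  if (!classes %in% c(2, 3)) stop("classes must be 2 or 3", call. = FALSE)
  if (input_size %% 4 != 0) stop("input_size must be divisible by 4", call. = FALSE)
  structure(list(filters = 64L, kernel = 3L, classes = as.integer(classes),
                 input_size = as.integer(input_size)),
            class = "unet_spec")
}

#' Training configuration
#'
#' Defaults follow the system's training protocol: initial learning rate
#' 0.001, at most 100 epochs, validation every 30 iterations, minibatch
#' size 32.  `max_iterations` and the early-stopping patience are
#' reduced-scale overrides for desk-scale runs.
#'
#' @param learning_rate initial SGD learning rate.
#' @param max_epochs maximum number of passes over the training set.
#' @param validation_frequency iterations between validation evaluations.
#' @param minibatch_size images per SGD step.
#' @param momentum SGD momentum coefficient.
#' @param seed integer seed controlling initialization and shuffling.
#' @param max_iterations hard cap on SGD iterations (`Inf` = none).
#' @param early_stop_patience stop after this many validations without
#'   improvement (`Inf` = train to `max_epochs`).
#' @param val_fraction fraction of the data held out for validation.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 100,
                         validation_frequency = 30, minibatch_size = 32,
                         momentum = 0.9, seed = 1L, max_iterations = Inf,
                         early_stop_patience = 10, val_fraction = 0.1) {
  structure(list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 validation_frequency = as.integer(validation_frequency),
                 minibatch_size = as.integer(minibatch_size), momentum = momentum,
                 seed = as.integer(seed), max_iterations = max_iterations,
                 early_stop_patience = early_stop_patience,
                 val_fraction = val_fraction),
            class = "train_config")
}

build_classifier_net <- function(spec, seed) {
  set.seed(seed)
  f <- spec$filters
  s <- spec$input_size %/% 8L
  layers <- list()
  cin <- 1L
  for (k in seq_along(f)) {
    layers <- c(layers, list(nn_layer_conv(cin, f[k], relu = TRUE),
                             nn_layer_bnorm(f[k]), list(type = "pool")))
    cin <- f[k]
  }
  layers <- c(layers, list(list(type = "flatten"),
                           nn_layer_dense(s * s * f[length(f)], spec$classes)))
  list(layers = layers)
}

build_unet_net <- function(spec, seed) {
  set.seed(seed)
  f <- spec$filters
  list(layers = list(
    nn_layer_conv(1L, f, relu = TRUE), list(type = "pool"),
    nn_layer_conv(f, f, relu = TRUE), list(type = "pool"),
    nn_layer_tconv(f, f, relu = TRUE),
    nn_layer_tconv(f, f, relu = TRUE),
    nn_layer_dense_pixel(f, spec$classes)))
}

nn_layer_dense_pixel <- function(nin, nout) {
  l <- nn_layer_dense(nin, nout)
  l$type <- "pixel_dense"
  l
}

# resize an image to the model's input side, re-binarizing if the source is
# binary so classifier inputs stay in the binary domain
resize_for_model <- function(img, size) {
  if (nrow(img) == size && ncol(img) == size) return(img)
  isbin <- all(img %in% c(0, 1))
  out <- resize_bilinear(img, size, size)
  if (isbin) out <- matrix(as.numeric(out > 0.5), size, size)
  out
}

#' Train a slice/component classifier
#'
#' Trains the two-class convolutional classifier on a classifier set (see
#' [build_cnn1_set()] and [build_cnn2_set()]).  Images are resized to the
#' spec's input size.  Training is deterministic given the seed.
#'
#' @param data a `classifier_set`.
#' @param spec a [classifier_spec()].
#' @param cfg a [train_config()].
#' @param verbose print validation progress.
#' @return object of class `lungseg_cnn` with the fitted weights and a
#'   training log (`$log`).
#' @export
train_classifier <- function(data, spec = classifier_spec(), cfg = train_config(),
                             verbose = FALSE) {
  if (!inherits(data, "classifier_set")) stop("data must be a classifier_set", call. = FALSE)
  if (length(data$items) == 0) stop("empty classifier set", call. = FALSE)
  cls <- vapply(data$items, function(it) it$class, character(1))
  if (length(unique(cls)) < 2)
    stop("both classes must be present to train the classifier", call. = FALSE)
  images <- lapply(data$items, function(it) resize_for_model(it$image, spec$input_size))
  y <- ifelse(cls == "lung", 1L, 2L)
  net <- build_classifier_net(spec, cfg$seed)
  fit <- nn_train(net, images, y, cfg, task = "class", verbose = verbose)
  structure(list(net = fit$net, spec = spec, cfg = cfg, log = fit$log,
                 iterations = fit$iterations, classes = c("lung", "none_lung"),
                 uid = next_uid()),
            class = "lungseg_cnn")
}

#' @export
print.lungseg_cnn <- function(x, ...) {
  cat(sprintf("conv-net classifier (%s filters, %dx%d input), %d SGD iterations\n",
              paste(x$spec$filters, collapse = "/"), x$spec$input_size,
              x$spec$input_size, x$iterations))
  if (length(x$log$val_acc))
    cat(sprintf("  final validation accuracy: %.3f\n", utils::tail(x$log$val_acc, 1)))
  invisible(x)
}

#' Classify one binary image
#'
#' @param model a trained `lungseg_cnn`.
#' @param img binary (or grayscale) matrix; resized with a warning if its
#'   size differs from the model input contract.
#' @return list with `class` (`"lung"` or `"none_lung"`) and `confidence`
#'   (softmax probability of the reported class, always in \[0.5, 1\]).
#' @export
predict_class <- function(model, img) {
  stopifnot(inherits(model, "lungseg_cnn"))
  s <- model$spec$input_size
  if (nrow(img) != s || ncol(img) != s) {
    warning("input resized to ", s, "x", s, " to match the model input contract")
    img <- resize_for_model(img, s)
  }
  fw <- nn_predict(model$net, img)
  p <- softmax_rows(fw$out)[1, ]
  k <- which.max(p)
  list(class = model$classes[k], confidence = unname(p[k]))
}

#' Train a segmentation U-net
#'
#' Trains the encoder--decoder network on a segmentation training set (see
#' [build_unet1_set()] and [build_unet2_set()]).  The label arity of the
#' data must match the spec's class count.  For edge-labeled sets the
#' per-pixel cross-entropy is class-weighted by inverse frequency, since
#' contour pixels are rare.
#'
#' @param data a `seg_train_set`.
#' @param spec a [unet_spec()].
#' @param cfg a [train_config()].
#' @param verbose print validation progress.
#' @return object of class `lungseg_unet`.
#' @export
train_unet <- function(data, spec = unet_spec(), cfg = train_config(),
                       verbose = FALSE) {
  if (!inherits(data, "seg_train_set")) stop("data must be a seg_train_set", call. = FALSE)
  if (length(data$items) == 0) stop("empty segmentation set", call. = FALSE)
  if (data$label_arity != spec$classes)
    stop("label arity (", data$label_arity, ") does not match spec classes (",
         spec$classes, ")", call. = FALSE)
  images <- lapply(data$items, function(it) resize_for_model(it$input, spec$input_size))
  labels <- lapply(data$items, function(it) {
    lab <- it$label
    if (nrow(lab) != spec$input_size) {
      lab <- matrix(as.integer(round(resize_bilinear(lab, spec$input_size,
                                                     spec$input_size))),
                    spec$input_size, spec$input_size)
    }
    lab + 1L  # classes 1..K for the loss
  })
  cw <- NULL
  if (isTRUE(data$edge_labels)) {
    # square-root inverse-frequency weights: plain inverse frequency makes
    # the rare contour class over-predicted (thick rings), unweighted loss
    # under-predicts it; the square root balances recall and thickness
    freq <- table(factor(unlist(lapply(labels, as.vector)), levels = seq_len(spec$classes)))
    cw <- sqrt(as.numeric(sum(freq) / (length(freq) * pmax(freq, 1))))
  }
  net <- build_unet_net(spec, cfg$seed)
  fit <- nn_train(net, images, labels, cfg, task = "pixel", class_weights = cw,
                  verbose = verbose)
  structure(list(net = fit$net, spec = spec, cfg = cfg, log = fit$log,
                 iterations = fit$iterations, config_id = data$config_id,
                 edge_labels = isTRUE(data$edge_labels), uid = next_uid()),
            class = "lungseg_unet")
}

#' @export
print.lungseg_unet <- function(x, ...) {
  cat(sprintf("U-net (%d filters, %d classes, %dx%d frames), %d SGD iterations\n",
              x$spec$filters, x$spec$classes, x$spec$input_size, x$spec$input_size,
              x$iterations))
  if (!is.null(x$config_id)) cat(sprintf("  training-data configuration: %s\n", x$config_id))
  invisible(x)
}

#' Predict a per-pixel label image
#'
#' Runs the U-net on a grayscale (or binary) image and returns the argmax
#' label image (values `0 .. classes-1`), at the input's own dimensions
#' (inputs are resized through the model frame if needed).
#'
#' @param model a trained `lungseg_unet`.
#' @param img numeric matrix in \[0, 1\].
#' @return integer label matrix with the same dimensions as `img`.
#' @export
predict_mask <- function(model, img) {
  stopifnot(inherits(model, "lungseg_unet"))
  s <- model$spec$input_size
  H <- nrow(img); W <- ncol(img)
  x <- resize_for_model(img, s)
  fw <- nn_predict(model$net, x)
  lab <- matrix(max.col(fw$out) - 1L, s, s)
  if (H != s || W != s) {
    # nearest-neighbour upsampling of labels back to the native size
    ri <- pmin(pmax(round((seq_len(H) - 0.5) * s / H + 0.5), 1), s)
    ci <- pmin(pmax(round((seq_len(W) - 0.5) * s / W + 0.5), 1), s)
    lab <- lab[ri, ci]
  }
  lab
}

#' Binary foreground view of a label image
#'
#' For multi-class label images the foreground is the class with the
#' highest mean intensity in the source image (the bright body in CT);
#' all other labels become background.
#'
#' @param labels integer label matrix from [predict_mask()].
#' @param img the grayscale image the labels were predicted from.
#' @return integer 0/1 matrix, 1 = bright foreground class.
#' @export
mask_binary_view <- function(labels, img) {
  vals <- sort(unique(as.vector(labels)))
  if (length(vals) == 1) return(matrix(0L, nrow(labels), ncol(labels)))
  means <- vapply(vals, function(v) mean(img[labels == v]), numeric(1))
  fg <- vals[which.max(means)]
  matrix(as.integer(labels == fg), nrow(labels), ncol(labels))
}

#' Save / load a trained model
#'
#' Saves the model in R's native serialization format with a JSON sidecar
#' describing the architecture, training configuration and seed.
#'
#' @param model a `lungseg_cnn` or `lungseg_unet`.
#' @param path file path for the checkpoint (sidecar written as
#'   `<path>.json`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(class = class(model), spec = unclass(model$spec),
               cfg = unclass(model$cfg), iterations = model$iterations)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
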