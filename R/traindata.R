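# Training-data factories for the four networks.  The manual
# visual-inspection steps of the original workflow are replaced by
# ground-truth-driven rules so the factories are automatic and testable.

new_classifier_set <- function(items, manifest) {
  structure(list(items = items, manifest = manifest), class = "classifier_set")
}

#' @export
print.classifier_set <- function(x, ...) {
  cls <- vapply(x$items, function(it) it$class, character(1))
  cat(sprintf("classifier set: %d items (%d lung, %d none_lung)\n",
              length(cls), sum(cls == "lung"), sum(cls == "none_lung")))
  invisible(x)
}

new_seg_train_set <- function(items, config_id, label_arity, edge_labels = FALSE) {
  structure(list(items = items, config_id = config_id, label_arity = label_arity,
                 edge_labels = edge_labels), class = "seg_train_set")
}

#' @export
print.seg_train_set <- function(x, ...) {
  cat(sprintf("segmentation training set: %d input/label pairs, %s, %d label classes%s\n",
              length(x$items),
              if (is.null(x$config_id)) "edge refinement data"
              else paste("configuration", x$config_id),
              x$label_arity, if (isTRUE(x$edge_labels)) " (edge labels)" else ""))
  invisible(x)
}

#' Build the slice-gate classifier training set
#'
#' Otsu-binarizes every slice and labels the binary image `lung` or
#' `none_lung` from the slice's ground-truth lung flag.
#'
#' @param slices list of `lungseg_slice` records.
#' @return a `classifier_set` of full-frame binary images.
#' @export
build_cnn1_set <- function(slices) {
  if (length(slices) == 0) stop("empty slice list", call. = FALSE)
  items <- lapply(slices, function(s) {
    list(image = otsu_binarize(s$image)$bin,
         class = if (isTRUE(s$contains_lung)) "lung" else "none_lung")
  })
  cls <- vapply(items, function(it) it$class, character(1))
  if (length(unique(cls)) < 2)
    warning("only one class present in the slice list; the set is single-class")
  new_classifier_set(items, data.frame(n = length(items),
                                       lung = sum(cls == "lung"),
                                       none_lung = sum(cls == "none_lung")))
}

#' Build the component-filter classifier training set
#'
#' For each slice, pixels are two-class k-means clustered on intensity and
#' the connected components of the dark class (excluding the border-touching
#' background) are rendered one per image at the full frame size.  A
#' component is labeled `lung` if its Dice overlap with any ground-truth
#' lung component reaches `overlap_threshold`, otherwise `none_lung`.
#'
#' @param slices list of `lungseg_slice` records carrying ground-truth masks.
#' @param overlap_threshold Dice overlap above which a component counts as
#'   lung (default 0.5).
#' @param min_area_frac components smaller than this fraction of the frame
#'   are dropped as specks.
#' @param seed RNG seed for the clustering.
#' @return a `classifier_set` of full-frame single-component binary images.
#' @export
build_cnn2_set <- function(slices, overlap_threshold = 0.5,
                           min_area_frac = 0.0005, seed = 1L) {
  if (length(slices) == 0) stop("empty slice list", call. = FALSE)
  items <- list()
  for (si in seq_along(slices)) {
    s <- slices[[si]]
    km <- clustering_tree(s$image, ks = 2, seed = seed + si)[[1]]
    dark <- matrix(as.integer(km == 1), nrow(km), ncol(km))
    cc <- connected_components(dark, 8)
    if (cc$count == 0) next
    H <- nrow(dark); W <- ncol(dark)
    gt_comps <- list()
    if (isTRUE(s$contains_lung)) {
      gcc <- connected_components(s$mask, 8)
      gt_comps <- lapply(seq_len(gcc$count), function(k)
        matrix(as.integer(gcc$labels == k), H, W))
    }
    sizes <- tabulate(cc$labels[cc$labels > 0], nbins = cc$count)
    border_labs <- unique(c(cc$labels[1, ], cc$labels[H, ],
                            cc$labels[, 1], cc$labels[, W]))
    for (k in seq_len(cc$count)) {
      if (k %in% border_labs) next
      if (sizes[k] < min_area_frac * H * W) next
      comp <- matrix(as.integer(cc$labels == k), H, W)
      is_lung <- any(vapply(gt_comps, function(g) dice_score(comp, g), numeric(1))
                     >= overlap_threshold)
      items[[length(items) + 1L]] <- list(image = comp,
                                          class = if (is_lung) "lung" else "none_lung")
    }
  }
  cls <- vapply(items, function(it) it$class, character(1))
  new_classifier_set(items, data.frame(n = length(items),
                                       lung = sum(cls == "lung"),
                                       none_lung = sum(cls == "none_lung")))
}

#' Build a segmentation training set for the binarizer U-net
#'
#' The five configurations of training data:
#' 1. ground-truth masks as both input and label;
#' 2. Otsu binary images as both input and label;
#' 3. foreground images (largest Otsu component, boundary included, holes
#'    unfilled) as both input and label;
#' 4. grayscale inputs with two-class k-means label images;
#' 5. grayscale inputs with three-class k-means label images.
#' Label classes are intensity-ordered (0 = darkest).
#'
#' @param slices list of `lungseg_slice` records (configuration 1 requires
#'   ground-truth masks).
#' @param config_id integer 1..5.
#' @param seed RNG seed for the k-means configurations.
#' @return a `seg_train_set`.
#' @export
build_unet1_set <- function(slices, config_id, seed = 1L) {
  if (!config_id %in% 1:5) stop("unknown config_id: ", config_id, call. = FALSE)
  if (length(slices) == 0) stop("empty slice list", call. = FALSE)
  items <- vector("list", length(slices))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (config_id == 1) {
      if (is.null(s$mask)) stop("configuration 1 requires ground-truth masks", call. = FALSE)
      inp <- s$mask + 0
      lab <- s$mask
    } else if (config_id == 2) {
      b <- otsu_binarize(s$image)$bin
      inp <- b + 0; lab <- b
    } else if (config_id == 3) {
      b <- otsu_binarize(s$image)$bin
      cc <- connected_components(b, 8)
      if (cc$count == 0) { fg <- b } else {
        sizes <- tabulate(cc$labels[cc$labels > 0], nbins = cc$count)
        fg <- matrix(as.integer(cc$labels == which.max(sizes)), nrow(b), ncol(b))
      }
      inp <- fg + 0; lab <- fg
    } else {
      k <- if (config_id == 4) 2L else 3L
      km <- clustering_tree(s$image, ks = k, seed = seed + i)[[1]]
      inp <- s$image
      lab <- km - 1L  # 0-based, intensity-ordered
    }
    items[[i]] <- list(input = inp, label = matrix(as.integer(lab), nrow(lab), ncol(lab)))
  }
  new_seg_train_set(items, config_id, label_arity = if (config_id == 5) 3L else 2L)
}

#' Build the contour-refinement training set
#'
#' Inputs are the binary lung regions as they are observable in the image:
#' ground-truth mask pixels that are dark under the slice's Otsu body
#' threshold, so pathology-brightened areas leave gaps in the input.
#' Labels are the Canny edge images of the ground-truth masks, which are
#' always closed contours.  Slices without lungs are skipped.
#'
#' @param slices list of `lungseg_slice` records carrying ground-truth masks.
#' @return a `seg_train_set` with edge labels.
#' @export
build_unet2_set <- function(slices) {
  if (length(slices) == 0) stop("empty slice list", call. = FALSE)
  items <- list()
  for (s in slices) {
    if (!isTRUE(s$contains_lung)) next
    body <- otsu_binarize(s$image)$bin
    inp <- matrix(as.integer(s$mask == 1L & body == 0L), nrow(s$mask), ncol(s$mask))
    lab <- canny_edges(s$mask)
    items[[length(items) + 1L]] <- list(input = inp + 0, label = lab)
  }
  if (length(items) == 0) stop("no slices with lungs in the input", call. = FALSE)
  new_seg_train_set(items, config_id = NULL, label_arity = 2L, edge_labels = TRUE)
}
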