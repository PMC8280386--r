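slices20 <- local({
  ds <- make_dataset(20, lung_fraction = 0.5, severity_range = c(0, 0.3),
                     image_size = 64, seed = 61)
  ds$slices
})

test_that("slice-gate set Otsu-binarizes and labels by lung presence", {
  set <- build_cnn1_set(slices20)
  expect_length(set$items, 20)
  expect_true(all(sapply(set$items, function(it) all(it$image %in% c(0, 1)))))
  cls <- sapply(set$items, function(it) it$class)
  truth <- sapply(slices20, function(s) if (s$contains_lung) "lung" else "none_lung")
  expect_identical(cls, truth)
  expect_error(build_cnn1_set(list()), "empty")
  expect_warning(build_cnn1_set(slices20[truth == "lung"]), "one class")
})

test_that("component-filter set labels components by ground-truth overlap", {
  s <- make_thorax_slice(phantom_params(128, seed = 9, noise_sigma = 0,
                                        gas_pockets = 1))
  set <- build_cnn2_set(list(s), seed = 1)
  cls <- sapply(set$items, function(it) it$class)
  expect_equal(sum(cls == "lung"), 2)  # left and right lung fields
  expect_gte(sum(cls == "none_lung"), 1)  # the gas pocket
  expect_true(all(sapply(set$items, function(it) all(it$image %in% c(0, 1)))))
  # one component per item
  expect_true(all(sapply(set$items, function(it)
    connected_components(it$image, 8)$count == 1)))

  s0 <- make_thorax_slice(phantom_params(128, seed = 10, lung_present = FALSE,
                                         noise_sigma = 0, gas_pockets = 2))
  set0 <- build_cnn2_set(list(s0), seed = 1)
  expect_true(all(sapply(set0$items, function(it) it$class) == "none_lung"))
})

test_that("binarizer training configurations follow their input/label contracts", {
  expect_error(build_unet1_set(slices20, 9), "unknown config")
  for (cid in 1:3) {
    set <- build_unet1_set(slices20[1:5], cid)
    expect_equal(set$label_arity, 2L)
    for (it in set$items) {
      expect_identical(matrix(as.integer(it$input), nrow(it$label)), it$label)
      expect_true(all(it$label %in% c(0L, 1L)))
    }
  }
  set4 <- build_unet1_set(slices20[1:5], 4, seed = 2)
  expect_equal(set4$label_arity, 2L)
  expect_false(all(set4$items[[1]]$input %in% c(0, 1)))  # grayscale inputs
  set5 <- build_unet1_set(slices20[1:5], 5, seed = 2)
  expect_equal(set5$label_arity, 3L)
  expect_setequal(unique(as.vector(set5$items[[1]]$label)), 0:2)
})

test_that("foreground configuration keeps the largest component with holes", {
  s <- make_thorax_slice(phantom_params(128, seed = 12, noise_sigma = 0))
  set3 <- build_unet1_set(list(s), 3)
  fg <- set3$items[[1]]$label
  # holes (the lungs) are preserved, the table artifact is dropped
  expect_equal(connected_components(fg, 8)$count, 1)
  expect_gt(sum(fill_holes(fg)) - sum(fg), 0)
})

test_that("refinement set pairs gap-ridden inputs with closed contour labels", {
  s_clean <- make_thorax_slice(phantom_params(128, seed = 13, noise_sigma = 0))
  s_path <- make_thorax_slice(phantom_params(128, seed = 13, noise_sigma = 0,
                                             pathology_severity = 0.3))
  set <- build_unet2_set(list(s_clean, s_path))
  expect_length(set$items, 2)
  expect_true(set$edge_labels)
  # severity 0: the input is the mask itself
  expect_gte(dice_score(matrix(as.integer(set$items[[1]]$input), 128, 128),
                        s_clean$mask), 0.99)
  # severity 0.3: pathology erases part of the observable lung region
  expect_lt(sum(set$items[[2]]$input), sum(s_path$mask))
  # labels lie within 1 px of the mask boundary
  for (k in 1:2) {
    s <- list(s_clean, s_path)[[k]]
    lab <- set$items[[k]]$label
    boundary <- s$mask & !lungseg:::erode3(s$mask)
    near <- lungseg:::dilate3(matrix(as.integer(boundary), 128, 128))
    expect_true(all(near[lab == 1] == 1))
  }
  # non-lung slices are skipped
  s0 <- make_thorax_slice(phantom_params(128, seed = 14, lung_present = FALSE))
  expect_length(build_unet2_set(list(s_clean, s0))$items, 1)
  expect_error(build_unet2_set(list(s0)), "no slices with lungs")
})

test_that("set construction is reproducible from the same slices and seed", {
  a <- build_cnn2_set(slices20[1:4], seed = 3)
  b <- build_cnn2_set(slices20[1:4], seed = 3)
  expect_identical(a$items, b$items)
  a5 <- build_unet1_set(slices20[1:4], 5, seed = 3)
  b5 <- build_unet1_set(slices20[1:4], 5, seed = 3)
  expect_identical(a5$items, b5$items)
})
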