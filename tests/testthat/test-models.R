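ns <- asNamespace("lungseg")

test_that("specifications enforce the published architecture constants", {
  spec <- classifier_spec(64)
  expect_identical(spec$filters, c(8L, 16L, 32L))
  expect_identical(spec$kernel, 3L)
  expect_identical(spec$classes, 2L)
  net <- ns$build_classifier_net(spec, seed = 1)
  convs <- Filter(function(l) l$type == "conv", net$layers)
  expect_identical(sapply(convs, function(l) ncol(l$W)), c(8L, 16L, 32L))
  expect_true(all(sapply(convs, function(l) nrow(l$W) / l$cin == 9)))

  uspec <- unet_spec(2, 64)
  unet <- ns$build_unet_net(uspec, seed = 1)
  cvs <- Filter(function(l) l$type %in% c("conv", "tconv"), unet$layers)
  expect_length(cvs, 4)
  expect_true(all(sapply(cvs, function(l) ncol(l$W)) == 64))
  expect_equal(sum(sapply(unet$layers, function(l) l$type == "pool")), 2)

  expect_error(unet_spec(4), "classes")
  expect_error(classifier_spec(50), "divisible")
})

test_that("training configuration defaults follow the published protocol", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$max_epochs, 100L)
  expect_equal(cfg$validation_frequency, 30L)
  expect_equal(cfg$minibatch_size, 32L)
})

test_that("classifier training validates inputs and fits separable data", {
  ds <- make_dataset(24, lung_fraction = 0.5, image_size = 64, seed = 91)
  set <- build_cnn1_set(ds$slices)
  expect_error(train_classifier(list()), "classifier_set")
  one_class <- set
  one_class$items <- Filter(function(it) it$class == "lung", set$items)
  expect_error(train_classifier(one_class, classifier_spec(64)), "both classes")

  cfg <- train_config(seed = 5, max_iterations = 60, minibatch_size = 8)
  m <- train_classifier(set, classifier_spec(64), cfg)
  test <- make_dataset(16, lung_fraction = 0.5, image_size = 64, seed = 92)$slices
  pred <- sapply(test, function(s) predict_class(m, otsu_binarize(s$image)$bin))
  acc <- mean(unlist(pred["class", ]) ==
                ifelse(sapply(test, function(s) s$contains_lung),
                       "lung", "none_lung"))
  expect_gte(acc, 0.85)
  conf <- unlist(pred["confidence", ])
  expect_true(all(conf >= 0.5 & conf <= 1))
  # deterministic prediction
  img <- otsu_binarize(test[[1]]$image)$bin
  expect_identical(predict_class(m, img), predict_class(m, img))
  # size mismatch resized with a warning
  expect_warning(predict_class(m, matrix(0.4 + diag(48) * 0.5, 48, 48)),
                 "resized")
})

test_that("U-net training enforces label arity and predicts aligned label images", {
  ds <- make_dataset(10, lung_fraction = 1, image_size = 64, seed = 93)
  set5 <- build_unet1_set(ds$slices, 5, seed = 1)
  expect_error(train_unet(set5, unet_spec(2, 64)), "arity")
  cfg <- train_config(seed = 5, max_iterations = 25, minibatch_size = 4)
  m <- train_unet(set5, unet_spec(3, 64), cfg)
  lab <- predict_mask(m, ds$slices[[1]]$image)
  expect_identical(dim(lab), dim(ds$slices[[1]]$image))
  expect_true(all(lab %in% 0:2))
  expect_identical(lab, predict_mask(m, ds$slices[[1]]$image))
})

test_that("binary view picks the brightest class as foreground", {
  img <- matrix(c(rep(0.1, 8), rep(0.9, 8)), 4, 4)
  labels <- matrix(c(rep(0L, 8), rep(1L, 8)), 4, 4)
  bv <- mask_binary_view(labels, img)
  expect_identical(bv, matrix(as.integer(img > 0.5), 4, 4))
  # swapped label ids give the same view
  bv2 <- mask_binary_view(1L - labels, img)
  expect_identical(bv2, bv)
})

test_that("models round-trip through save/load with a JSON sidecar", {
  ds <- make_dataset(8, lung_fraction = 0.5, image_size = 64, seed = 94)
  set <- build_cnn1_set(ds$slices)
  m <- train_classifier(set, classifier_spec(64),
                        train_config(seed = 2, max_iterations = 5,
                                     minibatch_size = 4))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  img <- otsu_binarize(ds$slices[[1]]$image)$bin
  expect_identical(predict_class(m, img), predict_class(m2, img))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(unlist(side$spec$filters), c(8, 16, 32))
  unlink(c(path, paste0(path, ".json")))
})
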