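test_that("phantom slices are reproducible and seed-sensitive", {
  p7 <- phantom_params(64, seed = 7, noise_sigma = 0.02)
  s_a <- make_thorax_slice(p7)
  s_b <- make_thorax_slice(p7)
  expect_identical(s_a$image, s_b$image)
  expect_identical(s_a$mask, s_b$mask)
  s_c <- make_thorax_slice(phantom_params(64, seed = 8, noise_sigma = 0.02))
  expect_false(identical(s_a$image, s_c$image))
})

test_that("phantom invariants hold: mask/lung coupling and tissue contrast", {
  s0 <- make_thorax_slice(phantom_params(64, lung_present = FALSE, seed = 2))
  expect_false(s0$contains_lung)
  expect_equal(sum(s0$mask), 0)

  s1 <- make_thorax_slice(phantom_params(96, seed = 3, pathology_severity = 0.2,
                                         noise_sigma = 0.02))
  expect_true(s1$contains_lung)
  expect_gt(sum(s1$mask), 0)
  body <- fill_holes(otsu_binarize(s1$image)$bin)
  inside <- mean(s1$image[s1$mask == 1])
  outside <- mean(s1$image[body == 1 & s1$mask == 0])
  expect_lt(inside, outside)  # lungs are dark in CT
  expect_true(all(s1$image >= 0 & s1$image <= 1))
})

test_that("phantom parameter validation rejects bad geometry", {
  expect_error(phantom_params(32), "image_size")
  expect_error(phantom_params(128, body_ellipse = c(0.5, 0.5, 0.6, 0.4)),
               "does not fit")
  expect_error(phantom_params(128, pathology_severity = 1.5), "severity")
})

test_that("severity 0 slices are recovered by the classical operators", {
  for (i in 1:5) {
    s <- make_thorax_slice(phantom_params(128, seed = 50 + i, noise_sigma = 0,
                                          pathology_severity = 0))
    cand <- candidate_lung_region(s$image, otsu_binarize(s$image)$bin)
    expect_gte(dice_score(cand, s$mask), 0.98)
  }
})

test_that("pathology severity monotonically degrades the classical pipeline", {
  mean_dice <- sapply(c(0, 0.2, 0.4), function(sv) {
    mean(sapply(1:6, function(i) {
      s <- make_thorax_slice(phantom_params(128, seed = 70 + i, noise_sigma = 0,
                                            pathology_severity = sv))
      dice_score(candidate_lung_region(s$image, otsu_binarize(s$image)$bin),
                 s$mask)
    }))
  })
  expect_true(all(diff(mean_dice) <= 0))
})

test_that("dataset generation respects composition and is manifest-reproducible", {
  d0 <- make_dataset(10, lung_fraction = 0, image_size = 64, seed = 5)
  expect_length(d0$slices, 10)
  expect_true(all(!d0$manifest$contains_lung))
  expect_true(all(sapply(d0$slices, function(s) sum(s$mask) == 0)))

  d1 <- make_dataset(60, lung_fraction = 0.8, image_size = 64, seed = 1)
  expect_equal(nrow(d1$manifest), 60)
  n_lung <- sum(d1$manifest$contains_lung)
  expect_gt(n_lung, qbinom(0.001, 60, 0.8))
  expect_lt(n_lung, qbinom(0.999, 60, 0.8))

  d2 <- make_dataset(60, lung_fraction = 0.8, image_size = 64, seed = 1)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$slices[[17]]$image, d2$slices[[17]]$image)

  expect_setequal(unique(d1$manifest$split), c("train", "val", "test"))
})
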