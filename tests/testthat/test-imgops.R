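test_that("Otsu threshold separates a perfectly bimodal image", {
  img <- matrix(c(rep(0.1, 32), rep(0.9, 32)), 8, 8)
  res <- otsu_binarize(img)
  expect_gt(res$threshold, 0.1)
  expect_lt(res$threshold, 0.9)
  expect_identical(res$bin, matrix(as.integer(img == 0.9), 8, 8))
})

test_that("Otsu threshold equals the exhaustive between-class-variance search", {
  set.seed(3)
  for (i in 1:10) {
    img <- matrix(sample(0:255, 64 * 64, replace = TRUE) / 255, 64, 64)
    res <- otsu_binarize(img)
    expect_equal(res$threshold, otsu_exhaustive(img), tolerance = 1e-12)
  }
})

test_that("Otsu agrees with the EBImage implementation to within a bin width", {
  skip_if_not_installed("EBImage")
  set.seed(5)
  img <- matrix(runif(64 * 64), 64, 64)
  ours <- otsu_binarize(img)$threshold
  theirs <- EBImage::otsu(img, range = range(img))
  expect_lt(abs(ours - theirs), 2 * diff(range(img)) / 256)
})

test_that("Otsu rejects a constant image", {
  expect_error(otsu_binarize(matrix(0.5, 8, 8)), "degenerate")
})

test_that("k-means labeling recovers exact and mixture structure", {
  img <- matrix(c(rep(0.2, 40), rep(0.8, 24)), 8, 8)
  lab <- clustering_tree(img, ks = 2, seed = 1)[[1]]
  expect_identical(lab, matrix(ifelse(img == 0.2, 1L, 2L), 8, 8))

  set.seed(11)
  v <- c(rnorm(1500, 0.1, 0.02), rnorm(1500, 0.5, 0.02), rnorm(1096, 0.9, 0.02))
  img3 <- matrix(sample(v), 64, 64)
  lab3 <- clustering_tree(img3, ks = 3, seed = 2)[[1]]
  means <- sort(tapply(as.vector(img3), as.vector(lab3), mean))
  expect_true(all(abs(means - c(0.1, 0.5, 0.9)) < 0.05))

  expect_length(clustering_tree(img3, ks = c(2, 3), seed = 1), 2)
  expect_error(clustering_tree(matrix(c(0, 1), 2, 2), ks = 3, seed = 1),
               "degenerate")
})

test_that("connected components match the flood-fill oracle and label order", {
  expect_equal(connected_components(matrix(0L, 8, 8), 8)$count, 0)
  two <- matrix(0L, 7, 9); two[2:4, 2:4] <- 1L; two[2:4, 6:8] <- 1L
  expect_equal(connected_components(two, 4)$count, 2)
  expect_equal(connected_components(two, 8)$count, 2)
  # left square is met first in raster order
  expect_equal(unique(as.vector(connected_components(two, 8)$labels[2:4, 2:4])), 1L)

  diagpair <- matrix(0L, 5, 5); diagpair[2, 2] <- 1L; diagpair[3, 3] <- 1L
  expect_equal(connected_components(diagpair, 4)$count, 2)
  expect_equal(connected_components(diagpair, 8)$count, 1)

  set.seed(17)
  for (i in 1:10) {
    bin <- matrix(as.integer(runif(32 * 32) < 0.4), 32, 32)
    for (conn in c(4, 8))
      expect_equal(connected_components(bin, conn)$count, flood_count(bin, conn))
  }
})

test_that("connected components agree with EBImage's 4-connectivity labeling", {
  skip_if_not_installed("EBImage")
  set.seed(19)
  bin <- matrix(as.integer(runif(48 * 48) < 0.35), 48, 48)
  expect_equal(connected_components(bin, 4)$count, max(EBImage::bwlabel(bin)))
})

test_that("Canny edges trace region boundaries", {
  expect_identical(canny_edges(matrix(0L, 32, 32)), matrix(0L, 32, 32))
  d <- filled_disk(20, 128)
  npx <- sum(canny_edges(d))
  expect_lt(abs(npx - 2 * pi * 20), 0.25 * 2 * pi * 20)
  # a broken contour (arc gap) yields strictly fewer edge pixels than the
  # closed one
  ring <- matrix(as.integer(d & !filled_disk(16, 128)), 128, 128)
  broken <- ring
  broken[1:64, 64:128] <- 0L  # remove a quarter arc
  expect_lt(sum(canny_edges(broken)), sum(canny_edges(ring)))
})

test_that("hole filling implements the border-flood-fill definition", {
  ann <- filled_disk(20, 64); ann[filled_disk(10, 64) == 1] <- 0L
  expect_identical(fill_holes(ann), filled_disk(20, 64))
  # C-shape: the cavity is connected to the border through the gap
  cshape <- matrix(0L, 20, 20)
  cshape[5:15, 5:15] <- 1L; cshape[8:12, 8:15] <- 0L
  expect_identical(fill_holes(cshape), cshape)
  # blob with interior holes: output area = input + total hole area
  set.seed(23)
  blob <- filled_disk(22, 64)
  holes <- filled_disk(4, 64, 28, 28) | filled_disk(3, 64, 38, 36) |
    filled_disk(2, 64, 30, 40)
  blob2 <- matrix(as.integer(blob & !holes), 64, 64)
  expect_equal(sum(fill_holes(blob2)), sum(blob2) + sum(blob & holes))
  # idempotent and a superset of the input
  f1 <- fill_holes(blob2)
  expect_identical(fill_holes(f1), f1)
  expect_true(all(f1 >= blob2))
})

test_that("candidate lung region extracts enclosed dark cavities", {
  body <- filled_disk(25, 64)
  expect_equal(sum(candidate_lung_region(body + 0, body)), 0)
  sq <- matrix(0L, 64, 64); sq[28:36, 28:36] <- 1L
  body2 <- matrix(as.integer(body & !sq), 64, 64)
  expect_identical(candidate_lung_region(body2 + 0, body2), sq)
})

test_that("contour quality grows with region size and degrades when broken", {
  expect_equal(contour_quality(matrix(0L, 32, 32))$tau2, 0)
  taus <- sapply(c(10, 20, 40), function(r) contour_quality(filled_disk(r))$tau2)
  expect_true(all(diff(taus) > 0))
  # matched closed/broken phantom candidate at the same geometry
  closed <- make_thorax_slice(phantom_params(128, seed = 41, noise_sigma = 0))
  broken <- make_thorax_slice(phantom_params(128, seed = 41, noise_sigma = 0,
                                             pathology_severity = 0.4))
  cand_c <- candidate_lung_region(closed$image, otsu_binarize(closed$image)$bin)
  cand_b <- candidate_lung_region(broken$image, otsu_binarize(broken$image)$bin)
  expect_gt(contour_quality(cand_c)$tau2, contour_quality(cand_b)$tau2)
})

test_that("Dice matches set arithmetic and its invariants", {
  sq <- matrix(0L, 20, 20); sq[3:12, 3:12] <- 1L
  expect_equal(dice_score(sq, sq), 1)
  sq2 <- matrix(0L, 20, 20); sq2[3:12, 8:17] <- 1L
  expect_equal(dice_score(sq, sq2), 0.5)  # 10x10 square shifted by 5
  disj <- matrix(0L, 20, 20); disj[15:18, 15:18] <- 1L
  expect_equal(dice_score(sq, disj), 0)
  expect_equal(dice_score(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)
  expect_error(dice_score(sq, matrix(0L, 5, 5)), "dimensions")
  set.seed(29)
  for (i in 1:5) {
    X <- matrix(as.integer(runif(100) < 0.5), 10, 10)
    Y <- matrix(as.integer(runif(100) < 0.5), 10, 10)
    brute <- 2 * sum(X == 1 & Y == 1) / (sum(X) + sum(Y))
    expect_equal(dice_score(X, Y), brute)
    expect_equal(dice_score(X, Y), dice_score(Y, X))
    expect_true(dice_score(X, Y) >= 0 && dice_score(X, Y) <= 1)
  }
})
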