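test_that("quality score is bounded, zero for degenerate input, monotone in contrast", {
  expect_equal(quality_score(matrix(0.5, 32, 32)), 0)
  s <- make_thorax_slice(phantom_params(96, seed = 4, noise_sigma = 0.01))
  sc_full <- quality_score(s$image)
  expect_true(sc_full >= 0 && sc_full <= 1)
  low <- 0.5 + 0.5 * (s$image - 0.5)  # contrast gain 0.5
  expect_gt(sc_full, quality_score(low))
})

test_that("full-contrast phantom slices pass the gate, low-contrast ones fail it", {
  scores <- sapply(1:5, function(i) {
    s <- make_thorax_slice(phantom_params(128, seed = 80 + i, noise_sigma = 0.01))
    quality_score(s$image)
  })
  expect_true(all(scores >= 0.9))
  low_scores <- sapply(1:5, function(i) {
    s <- make_thorax_slice(phantom_params(128, seed = 80 + i, noise_sigma = 0.01,
                                          contrast_gain = 0.5))
    quality_score(s$image)
  })
  expect_true(all(low_scores < 0.9))
})

test_that("enhancement raises the score of low-contrast slices and preserves order", {
  s <- make_thorax_slice(phantom_params(128, seed = 85, noise_sigma = 0.01,
                                        contrast_gain = 0.5))
  enh <- enhance_contrast(s$image, beta = 4)
  expect_true(all(enh >= 0 & enh <= 1))
  expect_gt(quality_score(enh), quality_score(s$image))
  # strictly monotone map: pixel rank order preserved
  ord <- order(as.vector(s$image))
  expect_true(!is.unsorted(as.vector(enh)[ord]))
})

test_that("gate construction validates its parameters and is swappable", {
  expect_error(quality_gate(tau1 = 1.4), "tau1")
  expect_error(quality_gate(beta = -1), "beta")
  g <- quality_gate(score_fun = function(img) 0.42,
                    enhance_fun = function(img, beta) img * 0 + 0.5)
  expect_equal(g$score_fun(matrix(0, 2, 2)), 0.42)
  expect_equal(g$enhance_fun(matrix(0, 2, 2), 4)[1, 1], 0.5)
})
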