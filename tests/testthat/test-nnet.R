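# Correctness of the conv-net engine: kernels against plain-R reference
# implementations, analytic gradients against directional numeric
# derivatives, and determinism of the training loop.

ns <- asNamespace("lungseg")

# plain-R "valid in frame" 3x3 convolution reference
ref_conv <- function(X, Wt, b, H, W, relu) {
  Cin <- ncol(X); Cout <- ncol(Wt)
  Y <- matrix(0, H * W, Cout)
  for (r in 2:(H - 1)) for (c in 2:(W - 1)) {
    acc <- rep(0, Cout)
    for (ci in seq_len(Cin)) for (dc in -1:1) for (dr in -1:1) {
      w <- Wt[(ci - 1) * 9 + (dc + 1) * 3 + (dr + 1) + 1, ]
      acc <- acc + X[(c + dc - 1) * H + (r + dr), ci] * w
    }
    v <- acc + b
    if (relu) v <- pmax(v, 0)
    Y[(c - 1) * H + r, ] <- v
  }
  Y
}

test_that("convolution kernel matches a direct reference implementation", {
  set.seed(31)
  H <- 7; W <- 6; Cin <- 2; Cout <- 3
  X <- matrix(rnorm(H * W * Cin), H * W, Cin)
  Wt <- matrix(rnorm(9 * Cin * Cout, 0, 0.3), 9 * Cin, Cout)
  b <- rnorm(Cout, 0, 0.1)
  for (relu in c(FALSE, TRUE)) {
    Y <- ns$cpp_conv_fwd(X, Wt, b, H, W, 1L, relu)
    expect_equal(Y, ref_conv(X, Wt, b, H, W, relu), tolerance = 1e-5)
  }
})

test_that("transposed convolution equals zero-stuffed upsampling + convolution", {
  set.seed(37)
  H <- 5; W <- 4; Cin <- 2; Cout <- 2
  X <- matrix(rnorm(H * W * Cin), H * W, Cin)
  Wt <- matrix(rnorm(9 * Cin * Cout, 0, 0.3), 9 * Cin, Cout)
  b <- rnorm(Cout, 0, 0.1)
  U <- matrix(0, 4 * H * W, Cin)
  for (ci in seq_len(Cin)) {
    u <- matrix(0, 2 * H, 2 * W)
    u[seq(1, 2 * H, 2), seq(1, 2 * W, 2)] <- matrix(X[, ci], H, W)
    U[, ci] <- as.vector(u)
  }
  Y <- ns$cpp_tconv_fwd(X, Wt, b, H, W, 1L, FALSE)
  expect_equal(Y, ref_conv(U, Wt, b, 2 * H, 2 * W, FALSE), tolerance = 1e-5)
})

test_that("max pooling halves the frame and routes gradients to the argmax", {
  set.seed(41)
  H <- 6; W <- 4
  X <- matrix(rnorm(H * W * 2), H * W, 2)
  p <- ns$cpp_pool_fwd(X, H, W, 1L)
  expect_equal(dim(p$Y), c(H * W / 4, 2))
  ref <- sapply(1:2, function(ci) {
    m <- matrix(X[, ci], H, W)
    as.vector(sapply(seq(1, W, 2), function(j)
      sapply(seq(1, H, 2), function(i) max(m[i:(i + 1), j:(j + 1)]))))
  })
  expect_equal(unname(p$Y), unname(ref))
  dY <- matrix(1, nrow(p$Y), 2)
  dX <- ns$cpp_pool_bwd(dY, p$idx, H, W, 1L)
  expect_equal(colSums(dX), colSums(dY))  # mass conserved
  expect_equal(sum(dX != 0), length(dY))  # exactly one winner per window
})

test_that("analytic gradients match directional numeric derivatives", {
  set.seed(42)
  net <- list(layers = list(
    ns$nn_layer_conv(1L, 4L), list(type = "pool"),
    ns$nn_layer_conv(4L, 4L), list(type = "pool"),
    ns$nn_layer_tconv(4L, 4L), ns$nn_layer_tconv(4L, 4L),
    ns$nn_layer_dense_pixel(4L, 2L)))
  for (li in c(1, 3, 5, 6, 7))
    net$layers[[li]]$b <- rnorm(length(net$layers[[li]]$b), 0, 0.05)
  B <- 2; H <- 8; W <- 8
  X <- matrix(runif(B * H * W), ncol = 1)
  y <- sample(1:2, B * H * W, TRUE)
  lossfun <- function(n) {
    fw <- ns$nn_forward(n, X, H, W, B, TRUE)
    ns$loss_pixel(fw$out, y)$loss
  }
  fw <- ns$nn_forward(net, X, H, W, B, TRUE)
  gr <- ns$nn_backward(net, fw$caches, ns$loss_pixel(fw$out, y)$dZ)
  d <- lapply(seq_along(net$layers), function(li) {
    g <- gr[[li]]
    if (is.null(g)) return(NULL)
    lapply(g, function(x) stats::rnorm(length(x)))
  })
  shift <- function(s) {
    n <- net
    for (li in seq_along(n$layers)) if (!is.null(d[[li]]))
      for (nm in names(d[[li]]))
        n$layers[[li]][[nm]] <- n$layers[[li]][[nm]] + s * d[[li]][[nm]]
    n
  }
  eps <- 1e-4
  num <- (lossfun(shift(eps)) - lossfun(shift(-eps))) / (2 * eps)
  ana <- 0
  for (li in seq_along(net$layers)) if (!is.null(d[[li]]))
    for (nm in names(d[[li]])) ana <- ana + sum(gr[[li]][[nm]] * d[[li]][[nm]])
  expect_lt(abs(num - ana) / max(abs(num), abs(ana)), 1e-2)
})

test_that("batch normalization gradients are exact", {
  set.seed(5)
  net <- list(layers = list(ns$nn_layer_conv(1L, 3L), ns$nn_layer_bnorm(3L),
                            list(type = "flatten"),
                            ns$nn_layer_dense(8 * 8 * 3L, 2L)))
  net$layers[[1]]$b <- rnorm(3, 0, 0.05)
  X <- matrix(runif(4 * 8 * 8), ncol = 1); y <- c(1L, 2L, 1L, 2L)
  lossfun <- function(n) {
    fw <- ns$nn_forward(n, X, 8, 8, 4, TRUE)
    ns$loss_class(fw$out, y)$loss
  }
  fw <- ns$nn_forward(net, X, 8, 8, 4, TRUE)
  gr <- ns$nn_backward(net, fw$caches, ns$loss_class(fw$out, y)$dZ)
  g2 <- gr[[2]]
  for (nm in c("gamma", "beta")) {
    for (i in seq_len(3)) {
      eps <- 1e-4
      n1 <- net; n1$layers[[2]][[nm]][i] <- net$layers[[2]][[nm]][i] + eps
      n2 <- net; n2$layers[[2]][[nm]][i] <- net$layers[[2]][[nm]][i] - eps
      num <- (lossfun(n1) - lossfun(n2)) / (2 * eps)
      expect_equal(g2[[nm]][i], num, tolerance = 1e-3)
    }
  }
})

test_that("training is deterministic under a fixed seed", {
  set.seed(99)
  imgs <- lapply(1:12, function(i) matrix(runif(16 * 16), 16, 16))
  y <- rep(1:2, 6)
  run <- function() {
    net <- ns$build_classifier_net(classifier_spec(16), seed = 4)
    ns$nn_train(net, imgs, y, train_config(seed = 4, max_iterations = 10,
                                           minibatch_size = 4),
                task = "class")
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(f1$net$layers[[1]]$W, f2$net$layers[[1]]$W)
})
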