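# Minimal CPU conv-net engine backing the classifier and U-net models.
#
# A feature-map batch is a (B*H*W) x C matrix: image b occupies rows
# ((b-1)*H*W + 1):(b*H*W), pixels in column-major order within the frame.
# 3x3 convolutions are "valid" convolutions embedded in a fixed frame (the
# 1-px border, where the window would leave the frame, is zero), so spatial
# alignment with the input is automatic.  All randomness (initialization,
# shuffling) goes through R's RNG; the compiled kernels are deterministic.

nn_layer_conv <- function(cin, cout, relu = TRUE) {
  list(type = "conv", cin = cin, cout = cout, relu = relu,
       W = matrix(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))), 9 * cin, cout),
       b = rep(0, cout))
}

nn_layer_tconv <- function(cin, cout, relu = TRUE) {
  list(type = "tconv", cin = cin, cout = cout, relu = relu,
       W = matrix(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))), 9 * cin, cout),
       b = rep(0, cout))
}

nn_layer_bnorm <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "bnorm", gamma = rep(1, c), beta = rep(0, c),
       rmean = rep(0, c), rvar = rep(1, c), momentum = momentum, eps = eps)
}

nn_layer_dense <- function(nin, nout) {
  list(type = "dense", W = matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout),
       b = rep(0, nout))
}

# forward pass; returns list(out, shape, caches, net) -- net returned because
# batch norm updates its running statistics in training mode
nn_forward <- function(net, X, H, W, B, train = TRUE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      Y <- cpp_conv_fwd(X, l$W, l$b, H, W, B, l$relu)
      caches[[i]] <- list(X = X, Y = Y, H = H, W = W, B = B)
      X <- Y
    } else if (l$type == "tconv") {
      Y <- cpp_tconv_fwd(X, l$W, l$b, H, W, B, l$relu)
      caches[[i]] <- list(X = X, Y = Y, H = H, W = W, B = B)
      X <- Y
      H <- 2L * H; W <- 2L * W
    } else if (l$type == "pool") {
      p <- cpp_pool_fwd(X, H, W, B)
      caches[[i]] <- list(idx = p$idx, H = H, W = W, B = B)
      X <- p$Y
      H <- H %/% 2L; W <- W %/% 2L
    } else if (l$type == "relu") {
      caches[[i]] <- list(mask = X > 0)
      X <- X * caches[[i]]$mask
    } else if (l$type == "bnorm") {
      if (train) {
        mu <- colMeans(X)
        xc <- sweep(X, 2, mu)
        v <- colMeans(xc^2)
        net$layers[[i]]$rmean <- (1 - l$momentum) * l$rmean + l$momentum * mu
        net$layers[[i]]$rvar <- (1 - l$momentum) * l$rvar + l$momentum * v
      } else {
        mu <- l$rmean; v <- l$rvar
        xc <- sweep(X, 2, mu)
      }
      istd <- 1 / sqrt(v + l$eps)
      xhat <- sweep(xc, 2, istd, `*`)
      caches[[i]] <- list(xhat = xhat, istd = istd, xc = xc)
      X <- sweep(sweep(xhat, 2, l$gamma, `*`), 2, l$beta, `+`)
    } else if (l$type == "flatten") {
      caches[[i]] <- list(H = H, W = W, B = B, C = ncol(X))
      HW <- H * W
      F <- matrix(0, B, HW * ncol(X))
      for (b in seq_len(B)) F[b, ] <- as.vector(X[((b - 1) * HW + 1):(b * HW), ])
      X <- F
      H <- 1L; W <- 1L
    } else if (l$type == "dense") {
      caches[[i]] <- list(X = X)
      X <- sweep(X %*% l$W, 2, l$b, `+`)
    } else if (l$type == "pixel_dense") {
      caches[[i]] <- list(X = X)
      X <- sweep(X %*% l$W, 2, l$b, `+`)
    } else stop("unknown layer type: ", l$type)
  }
  list(out = X, H = H, W = W, B = B, caches = caches, net = net)
}

nn_backward <- function(net, caches, dX) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]; cc <- caches[[i]]
    if (l$type == "conv") {
      g <- cpp_conv_bwd(cc$X, l$W, cc$Y, dX, cc$H, cc$W, cc$B, l$relu)
      grads[[i]] <- list(W = g$dW, b = as.vector(g$db))
      dX <- g$dX
    } else if (l$type == "tconv") {
      g <- cpp_tconv_bwd(cc$X, l$W, cc$Y, dX, cc$H, cc$W, cc$B, l$relu)
      grads[[i]] <- list(W = g$dW, b = as.vector(g$db))
      dX <- g$dX
    } else if (l$type == "pool") {
      dX <- cpp_pool_bwd(dX, cc$idx, cc$H, cc$W, cc$B)
    } else if (l$type == "relu") {
      dX <- dX * cc$mask
    } else if (l$type == "bnorm") {
      m <- nrow(dX)
      dgamma <- colSums(dX * cc$xhat)
      dbeta <- colSums(dX)
      dxhat <- sweep(dX, 2, l$gamma, `*`)
      t1 <- sweep(dxhat, 2, colSums(dxhat) / m)
      t2 <- sweep(cc$xhat, 2, colSums(dxhat * cc$xhat) / m, `*`)
      dX <- sweep(t1 - t2, 2, cc$istd, `*`)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
    } else if (l$type == "flatten") {
      HW <- cc$H * cc$W
      U <- matrix(0, cc$B * HW, cc$C)
      for (b in seq_len(cc$B))
        U[((b - 1) * HW + 1):(b * HW), ] <- matrix(dX[b, ], HW, cc$C)
      dX <- U
    } else if (l$type %in% c("dense", "pixel_dense")) {
      grads[[i]] <- list(W = crossprod(cc$X, dX), b = colSums(dX))
      dX <- tcrossprod(dX, l$W)
    }
  }
  grads
}

# Adam update (adaptive moment estimation); state holds first/second moments
nn_adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (is.null(state[[i]])) state[[i]] <- list()
    for (nm in names(g)) {
      m <- state[[i]][[paste0("m_", nm)]]
      v <- state[[i]][[paste0("v_", nm)]]
      if (is.null(m)) { m <- g[[nm]] * 0; v <- m }
      m <- beta1 * m + (1 - beta1) * g[[nm]]
      v <- beta2 * v + (1 - beta2) * g[[nm]]^2
      state[[i]][[paste0("m_", nm)]] <- m
      state[[i]][[paste0("v_", nm)]] <- v
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      net$layers[[i]][[nm]] <- net$layers[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}

# losses ---------------------------------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# classification cross-entropy; y integer 1..K
loss_class <- function(Z, y) {
  P <- softmax_rows(Z)
  n <- nrow(Z)
  loss <- -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(n), y)] <- dZ[cbind(seq_len(n), y)] - 1
  list(loss = loss, dZ = dZ / n)
}

# per-pixel cross-entropy with optional class weights; y integer 1..K
loss_pixel <- function(Z, y, class_weights = NULL) {
  K <- ncol(Z)
  if (is.null(class_weights)) class_weights <- rep(1, K)
  P <- softmax_rows(Z)
  n <- nrow(Z)
  wi <- class_weights[y]
  sw <- sum(wi)
  loss <- -sum(wi * log(pmax(P[cbind(seq_len(n), y)], 1e-12))) / sw
  dZ <- P * wi
  dZ[cbind(seq_len(n), y)] <- dZ[cbind(seq_len(n), y)] - wi
  list(loss = loss, dZ = dZ / sw)
}

# batch assembly -------------------------------------------------------------

stack_images <- function(imgs) {
  matrix(unlist(lapply(imgs, as.vector), use.names = FALSE), ncol = 1)
}

stack_labels <- function(labs) {
  as.integer(unlist(lapply(labs, as.vector), use.names = FALSE))
}

# generic SGD training loop shared by the classifier and U-net trainers.
# task = "class": labels y is an integer vector (one per image)
# task = "pixel": labels is a list of integer label matrices (1..K)
nn_train <- function(net, images, labels, cfg, task = c("class", "pixel"),
                     class_weights = NULL, val_idx = NULL, verbose = FALSE) {
  task <- match.arg(task)
  n <- length(images)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  set.seed(cfg$seed)
  if (is.null(val_idx) && cfg$val_fraction > 0)
    val_idx <- sample.int(n, max(1L, floor(cfg$val_fraction * n)))
  tr_idx <- setdiff(seq_len(n), val_idx)
  opt_state <- vector("list", length(net$layers))
  log <- list(iter = integer(), loss = numeric(), val_iter = integer(),
              val_loss = numeric(), val_acc = numeric())
  iter <- 0L
  best_val <- Inf; since_best <- 0L
  batch <- min(cfg$minibatch_size, length(tr_idx))

  eval_set <- function(idx) {
    tot_loss <- 0; tot_acc <- 0; tot_n <- 0
    for (start in seq(1, length(idx), by = batch)) {
      sel <- idx[start:min(start + batch - 1, length(idx))]
      X <- stack_images(images[sel])
      fw <- nn_forward(net, X, H, W, length(sel), train = FALSE)
      if (task == "class") {
        y <- labels[sel]
        ls <- loss_class(fw$out, y)
        acc <- mean(max.col(fw$out) == y)
      } else {
        y <- stack_labels(labels[sel])
        ls <- loss_pixel(fw$out, y, class_weights)
        acc <- mean(max.col(fw$out) == y)
      }
      m <- length(sel)
      tot_loss <- tot_loss + ls$loss * m; tot_acc <- tot_acc + acc * m; tot_n <- tot_n + m
    }
    c(loss = tot_loss / tot_n, acc = tot_acc / tot_n)
  }

  done <- FALSE
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample(tr_idx)
    for (start in seq(1, length(perm), by = batch)) {
      sel <- perm[start:min(start + batch - 1, length(perm))]
      B <- length(sel)
      X <- stack_images(images[sel])
      fw <- nn_forward(net, X, H, W, B, train = TRUE)
      net <- fw$net
      if (task == "class") {
        ls <- loss_class(fw$out, labels[sel])
      } else {
        ls <- loss_pixel(fw$out, stack_labels(labels[sel]), class_weights)
      }
      grads <- nn_backward(net, fw$caches, ls$dZ)
      iter <- iter + 1L
      st <- nn_adam_step(net, grads, opt_state, cfg$learning_rate, iter)
      net <- st$net; opt_state <- st$state
      log$iter <- c(log$iter, iter); log$loss <- c(log$loss, ls$loss)
      if (length(val_idx) > 0 && iter %% cfg$validation_frequency == 0L) {
        ev <- eval_set(val_idx)
        log$val_iter <- c(log$val_iter, iter)
        log$val_loss <- c(log$val_loss, ev["loss"])
        log$val_acc <- c(log$val_acc, ev["acc"])
        if (verbose)
          message(sprintf("iter %d: train loss %.4f, val loss %.4f, val acc %.4f",
                          iter, ls$loss, ev["loss"], ev["acc"]))
        if (ev["loss"] < best_val - 1e-6) { best_val <- ev["loss"]; since_best <- 0L }
        else since_best <- since_best + 1L
        if (is.finite(cfg$early_stop_patience) && since_best >= cfg$early_stop_patience) {
          done <- TRUE; break
        }
      }
      if (iter >= cfg$max_iterations) { done <- TRUE; break }
    }
    if (done) break
  }
  list(net = net, log = log, iterations = iter)
}

nn_predict <- function(net, img, H = nrow(img), W = ncol(img)) {
  fw <- nn_forward(net, matrix(as.vector(img), ncol = 1), H, W, 1L, train = FALSE)
  fw
}
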