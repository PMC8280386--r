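# Shared fixtures: simple shapes, brute-force oracles, and lazily built
# (and cached) trained models for the pipeline tests.

filled_disk <- function(r, n = 128, cy = n / 2, cx = n / 2) {
  dy <- matrix(seq_len(n) - cy, n, n)
  dx <- matrix(seq_len(n) - cx, n, n, byrow = TRUE)
  matrix(as.integer(dy^2 + dx^2 <= r^2), n, n)
}

# brute-force flood-fill component count (independent of the C++ labeling)
flood_count <- function(bin, connectivity) {
  H <- nrow(bin); W <- ncol(bin)
  seen <- matrix(FALSE, H, W)
  if (connectivity == 8) {
    nb <- cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  count <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (bin[r, c] == 0 || seen[r, c]) next
    count <- count + 1L
    queue <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            bin[rr, cc] == 1 && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  count
}

# exhaustive-search Otsu threshold over all 256 histogram cut points
otsu_exhaustive <- function(img) {
  lo <- min(img); hi <- max(img)
  nb <- 256L
  wbin <- (hi - lo) / nb
  idx <- pmin(as.integer(floor((img - lo) / wbin)), nb - 1L)
  centers <- lo + (0:(nb - 1) + 0.5) * wbin
  best <- -Inf; bestk <- NA
  for (k in 0:(nb - 2)) {
    g0 <- idx <= k; g1 <- !g0
    n0 <- sum(g0); n1 <- sum(g1)
    if (n0 == 0 || n1 == 0) next
    mu0 <- mean(centers[idx[g0] + 1L]); mu1 <- mean(centers[idx[g1] + 1L])
    sb <- (n0 / length(idx)) * (n1 / length(idx)) * (mu0 - mu1)^2
    if (sb > best + 1e-15) { best <- sb; bestk <- k }
  }
  lo + (bestk + 1) * wbin
}

# lazily trained small system shared by pipeline and acceptance tests
.test_cache <- new.env(parent = emptyenv())

mini_system <- function() {
  if (is.null(.test_cache$mini)) {
    ds <- make_dataset(48, lung_fraction = 0.75, severity_range = c(0, 0.3),
                       image_size = 64, split = c(train = 1, val = 0, test = 0),
                       seed = 1301)
    .test_cache$mini <- lungseg_fit(
      ds$slices, config_id = 2,
      train_cfg = train_config(seed = 7, minibatch_size = 8),
      iters = c(cnn1 = 60, unet1 = 50, unet2 = 110, cnn2 = 60))
  }
  .test_cache$mini
}
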