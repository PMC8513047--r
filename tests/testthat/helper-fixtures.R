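# Shared fixtures, all built in code.

the_specs <- read_class_specs()

# digital shapes on small grids
# centers sit between pixel centers (the renderer's generic case), so the
# digital bounding box is not inflated by boundary points landing exactly
# on pixel centers
make_disk <- function(r = 60, pad = 11) {
  side <- 2 * r + pad * 2
  ctr <- r + pad + 0.5
  g <- expand.grid(i = 1:side, j = 1:side)
  matrix((g$i - ctr)^2 + (g$j - ctr)^2 <= r^2, side, side)
}

make_ellipse <- function(a = 40, b = 20, theta = 0, pad = 11) {
  side <- 2 * max(a, b) + 2 * pad
  ctr <- max(a, b) + pad + 0.5
  g <- expand.grid(i = 1:side, j = 1:side)
  u <-  cos(theta) * (g$i - ctr) + sin(theta) * (g$j - ctr)
  v <- -sin(theta) * (g$i - ctr) + cos(theta) * (g$j - ctr)
  matrix(u^2 / b^2 + v^2 / a^2 <= 1, side, side)
}

make_rect <- function(w = 160, h = 40, pad = 21) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

# two ellipses whose centers are close enough to overlap by a fraction of
# the minor axis, for watershed tests
make_touching_pair <- function(a = 30, b = 12, overlap_frac = 0.15) {
  side_r <- 2 * b + 40
  side_c <- 4 * a + 40
  ctr_r <- side_r / 2
  d <- 2 * a - overlap_frac * 2 * b
  c1 <- side_c / 2 - d / 2; c2 <- side_c / 2 + d / 2
  g <- expand.grid(i = 1:side_r, j = 1:side_c)
  m1 <- (g$i - ctr_r)^2 / b^2 + (g$j - c1)^2 / a^2 <= 1
  m2 <- (g$i - ctr_r)^2 / b^2 + (g$j - c2)^2 / a^2 <= 1
  matrix(m1 | m2, side_r, side_c)
}

# analytic foreground mask reconstructed from a scene's truth records
analytic_scene_mask <- function(scene) {
  H <- dim(scene$image)[1]; W <- dim(scene$image)[2]
  mask <- matrix(FALSE, H, W)
  tr <- scene$truth
  for (i in seq_len(nrow(tr))) {
    r <- ceiling(tr$semi_major[i] * (1 + tr$waviness[i])) + 1
    rows <- max(1, floor(tr$row[i]) - r):min(H, ceiling(tr$row[i]) + r)
    cols <- max(1, floor(tr$col[i]) - r):min(W, ceiling(tr$col[i]) + r)
    u1 <- outer(rows - tr$row[i], rep(1, length(cols)))
    u2 <- outer(rep(1, length(rows)), cols - tr$col[i])
    th <- tr$orientation[i]
    p1 <- ( cos(th) * u1 + sin(th) * u2) / tr$semi_major[i]
    p2 <- (-sin(th) * u1 + cos(th) * u2) / tr$semi_minor[i]
    # phase is not stored in truth; ignore the (sub-pixel) waviness term
    mask[rows, cols] <- mask[rows, cols] | (p1^2 + p2^2 <= 1)
  }
  mask
}

# match detected grains to truth rows by nearest centroid; returns the
# index into detections for each truth row
match_truth <- function(labels, truth) {
  n <- max(labels)
  cent <- t(vapply(seq_len(n), function(k) {
    px <- which(labels == k, arr.ind = TRUE)
    colMeans(px)
  }, numeric(2)))
  vapply(seq_len(nrow(truth)), function(i)
    which.min((cent[, 1] - truth$row[i])^2 + (cent[, 2] - truth$col[i])^2),
    integer(1))
}

# fast training control for tests
test_control <- grain_net_control(max_epochs = 80)

# independent brute-force Tukey-Kramer oracle: studentized-range p-values
# computed directly from group summaries
tukey_oracle <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g); N <- length(y)
  means <- tapply(y, g, mean); ns <- tapply(y, g, length)
  mse <- sum((y - means[g])^2) / (N - k)
  out <- list()
  lv <- levels(g)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[[i]] - means[[j]]) / se
    out[[paste(lv[j], lv[i], sep = "-")]] <-
      as.numeric(stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE))
  }
  unlist(out)
}
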