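# Synthetic grain scene renderer.
#
# Grains are drawn as boundary-perturbed ellipses: in ellipse-normalized
# polar coordinates the boundary is rho(t) = 1 + w * cos(6 t + phase), a
# low-order sinusoidal waviness that exercises the fractal-dimension and
# perimeter estimators without leaving the bold-to-slender family. A pixel
# is foreground iff its center lies inside the analytic boundary; the same
# convention is assumed by the feature extractor.

#' Render a synthetic grain scene with analytic ground truth
#'
#' Draws `n_per_class` grains per class as randomly posed, boundary-wavy
#' ellipses filled with the class CIELab color (converted to sRGB) plus
#' per-pixel Gaussian noise, over a uniform background whose polarity is
#' chosen to contrast with the grains (dark background for light grains and
#' vice versa). Grain placement is non-touching by rejection sampling with a
#' dilation margin; an optional touching mode places a fraction of grains in
#' pairs that overlap by 15% of the smaller minor axis, for watershed
#' testing.
#'
#' @param specs A `class_specs` list (see [read_class_specs()]), or a subset
#'   of one.
#' @param n_per_class Number of grains rendered per class (>= 1).
#' @param image_size Integer `c(height, width)` in pixels.
#' @param touching_fraction Fraction of grains placed as touching pairs, in
#'   \[0, 1\].
#' @param seed Integer seed; fixed seed gives a byte-identical scene.
#' @param noise_sd Per-pixel, per-channel Gaussian noise SD in 8-bit digital
#'   counts (default 2).
#' @param margin Dilation margin in pixels enforced between non-touching
#'   grains (default 3).
#' @return An object of class `grain_scene`: list with `image` (height x
#'   width x 3 array in \[0,1\]), `truth` (one row per grain: class, pose,
#'   sampled color, and analytic area/perimeter/aspect/extent/circularity),
#'   `touching_pairs` (two-column matrix of grain indices) and
#'   `polarity_used`.
#' @examples
#' specs <- read_class_specs()
#' sc <- render_grain_scene(specs[1:2], n_per_class = 3, seed = 1)
#' nrow(sc$truth)  # 6
#' @export
render_grain_scene <- function(specs, n_per_class, image_size = c(480, 640),
                               touching_fraction = 0, seed = NULL,
                               noise_sd = 2, margin = 3) {
  if (length(specs) == 0L) stop("specs must be non-empty")
  stopifnot(n_per_class >= 1, touching_fraction >= 0, touching_fraction <= 1)
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  with_seed(seed, {
    polarity <- names(sort(table(vapply(specs, function(s)
      s$background_polarity, character(1))), decreasing = TRUE))[1]
    bg <- if (polarity == "dark") 0.02 else 0.94

    # sample per-grain parameters first, then place
    grains <- list()
    for (s in specs) for (k in seq_len(n_per_class)) {
      a  <- max(4, rnorm(1, s$geometry$semi_major$mean, s$geometry$semi_major$sd))
      ar <- max(1.05, rnorm(1, s$geometry$aspect_ratio$mean, s$geometry$aspect_ratio$sd))
      b  <- max(2, a / ar)
      w  <- min(0.15, max(0, rnorm(1, s$geometry$waviness$mean, s$geometry$waviness$sd)))
      lab <- c(L = min(100, max(0, rnorm(1, s$color$L$mean, s$color$L$sd))),
               a = rnorm(1, s$color$a$mean, s$color$a$sd),
               b = rnorm(1, s$color$b$mean, s$color$b$sd))
      grains[[length(grains) + 1L]] <- list(
        class_id = s$class_id, abbreviation = s$abbreviation,
        a = a, b = b, w = w, theta = runif(1, 0, pi),
        phase = runif(1, 0, 2 * pi), lab = lab)
    }
    n <- length(grains)
    grains <- grains[sample.int(n)]  # interleave classes spatially

    r_eff <- vapply(grains, function(g) g$a * (1 + g$w), numeric(1))
    n_pairs <- floor(touching_fraction * n / 2)
    centers <- matrix(NA_real_, n, 2)
    touching_pairs <- matrix(integer(0), 0, 2)

    place_one <- function(i, partner_of = NA) {
      g <- grains[[i]]
      if (H - r_eff[i] - 1 <= r_eff[i] + 2 || W - r_eff[i] - 1 <= r_eff[i] + 2)
        return(FALSE)
      for (attempt in seq_len(400)) {
        if (is.na(partner_of)) {
          c_new <- c(runif(1, r_eff[i] + 2, H - r_eff[i] - 1),
                     runif(1, r_eff[i] + 2, W - r_eff[i] - 1))
        } else {
          j <- partner_of
          dir <- grains[[j]]$theta
          d <- r_eff[i] + r_eff[j] - 0.15 * 2 * min(grains[[i]]$b, grains[[j]]$b)
          c_new <- centers[j, ] + d * c(cos(dir), sin(dir)) * sample(c(-1, 1), 1)
          grains[[i]]$theta <<- dir  # align pair along contact axis
          if (any(c_new < r_eff[i] + 2) || c_new[1] > H - r_eff[i] - 1 ||
              c_new[2] > W - r_eff[i] - 1) next
        }
        placed <- which(!is.na(centers[, 1]))
        placed <- setdiff(placed, partner_of)
        ok <- TRUE
        if (length(placed)) {
          dd <- sqrt((centers[placed, 1] - c_new[1])^2 +
                     (centers[placed, 2] - c_new[2])^2)
          ok <- all(dd >= r_eff[placed] + r_eff[i] + margin)
        }
        if (ok) { centers[i, ] <<- c_new; return(TRUE) }
      }
      FALSE
    }

    i <- 1L; pair_count <- 0L
    while (i <= n) {
      if (!place_one(i))
        stop("placement failure: image too small; placed ", i - 1L,
             " of ", n, " grains")
      if (pair_count < n_pairs && i < n) {
        if (place_one(i + 1L, partner_of = i)) {
          touching_pairs <- rbind(touching_pairs, c(i, i + 1L))
          pair_count <- pair_count + 1L
          i <- i + 1L
        }
      }
      i <- i + 1L
    }

    # paint
    img <- array(bg, dim = c(H, W, 3))
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      g <- grains[[i]]; ctr <- centers[i, ]
      rgb1 <- pmin(1, pmax(0, grDevices::convertColor(
        matrix(g$lab, 1, 3), from = "Lab", to = "sRGB")))
      r <- ceiling(r_eff[i]) + 1L
      rows <- max(1L, floor(ctr[1]) - r):min(H, ceiling(ctr[1]) + r)
      cols <- max(1L, floor(ctr[2]) - r):min(W, ceiling(ctr[2]) + r)
      u1 <- outer(rows - ctr[1], rep(1, length(cols)))
      u2 <- outer(rep(1, length(rows)), cols - ctr[2])
      p1 <- ( cos(g$theta) * u1 + sin(g$theta) * u2) / g$a
      p2 <- (-sin(g$theta) * u1 + cos(g$theta) * u2) / g$b
      m <- 1 + g$w * cos(6 * atan2(p2, p1) + g$phase)
      inside <- (p1^2 + p2^2) <= m^2
      idx <- which(inside, arr.ind = TRUE)
      if (nrow(idx)) for (ch in 1:3)
        img[cbind(rows[idx[, 1]], cols[idx[, 2]], ch)] <- rgb1[ch]

      truth[[i]] <- data.frame(
        grain_id = i, class_id = g$class_id, abbreviation = g$abbreviation,
        row = ctr[1], col = ctr[2], semi_major = g$a, semi_minor = g$b,
        orientation = g$theta, waviness = g$w,
        L = g$lab[1], a = g$lab[2], b = g$lab[3],
        t(grain_truth_shape(g)), stringsAsFactors = FALSE)
    }
    if (noise_sd > 0) {
      img <- img + array(rnorm(length(img), 0, noise_sd / 255), dim = dim(img))
      img <- pmin(pmax(img, 0), 1)
    }
    structure(list(image = img, truth = do.call(rbind, truth),
                   touching_pairs = touching_pairs, polarity_used = polarity),
              class = "grain_scene")
  })
}

# analytic shape descriptors of a wavy ellipse, by dense boundary sampling
grain_truth_shape <- function(g) {
  t <- seq(0, 2 * pi, length.out = 1441L)[-1441L]
  m <- 1 + g$w * cos(6 * t + g$phase)
  x <- g$a * m * cos(t); y <- g$b * m * sin(t)
  area <- g$a * g$b * pi * (1 + g$w^2 / 2)
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  xr <- cos(g$theta) * x - sin(g$theta) * y
  yr <- sin(g$theta) * x + cos(g$theta) * y
  bbox <- (max(xr) - min(xr)) * (max(yr) - min(yr))
  c(area_true = area, perim_true = per, ar_true = g$a / g$b,
    ext_true = area / bbox, cir_true = 4 * pi * area / per^2)
}

#' @export
print.grain_scene <- function(x, ...) {
  cat(sprintf("grain_scene: %d x %d px, %d grains (%d classes), %d touching pairs, %s background\n",
              dim(x$image)[1], dim(x$image)[2], nrow(x$truth),
              length(unique(x$truth$class_id)), nrow(x$touching_pairs),
              x$polarity_used))
  invisible(x)
}

#' Write a rendered scene as PNG plus a ground-truth JSON sidecar
#'
#' @param scene A `grain_scene`.
#' @param png_path Output PNG path; the sidecar is written next to it with
#'   extension `.truth.json`.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_scene <- function(scene, png_path) {
  png::writePNG(scene$image, png_path)
  sidecar <- sub("\\.png$", ".truth.json", png_path)
  jsonlite::write_json(
    list(polarity_used = scene$polarity_used,
         touching_pairs = scene$touching_pairs,
         truth = scene$truth),
    sidecar, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(c(png_path, sidecar))
}

#' Read a scene written by [write_scene()]
#'
#' @param png_path Path to the PNG; the `.truth.json` sidecar is read if
#'   present.
#' @return A `grain_scene` (with empty truth if no sidecar exists).
#' @export
read_scene <- function(png_path) {
  img <- png::readPNG(png_path)
  sidecar <- sub("\\.png$", ".truth.json", png_path)
  truth <- NULL; pairs <- matrix(integer(0), 0, 2); pol <- NA_character_
  if (file.exists(sidecar)) {
    side <- jsonlite::fromJSON(sidecar)
    truth <- as.data.frame(side$truth)
    pol <- side$polarity_used
    if (length(side$touching_pairs)) pairs <- matrix(side$touching_pairs, ncol = 2)
  }
  structure(list(image = img, truth = truth, touching_pairs = pairs,
                 polarity_used = pol), class = "grain_scene")
}
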