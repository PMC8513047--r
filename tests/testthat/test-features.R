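test_that("geometry of canonical digital shapes", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  g <- measure_geometry(sq, 1)
  expect_equal(g$A, 100)
  expect_equal(g$bbox_area, 100)
  expect_equal(unname(g$centroid), c(10.5, 10.5))

  el <- make_ellipse(a = 40, b = 20)
  g <- measure_geometry(el, 1)
  expect_equal(g$major, 80, tolerance = 0.02)
  expect_equal(g$minor, 40, tolerance = 0.02)

  one <- matrix(FALSE, 10, 10); one[5, 5] <- TRUE
  expect_equal(measure_geometry(one, 1)$A, 1)

  expect_error(measure_geometry(sq, 99), "not found")
})

test_that("circularity matches analytic values for disk, ellipse, rectangle", {
  expect_equal(circularity(measure_geometry(make_disk(60), 1)), 1,
               tolerance = 0.05)
  # 2:1 ellipse: 4*pi*A/P^2 with P from the elliptic-perimeter integral
  expect_equal(circularity(measure_geometry(make_ellipse(40, 20), 1)), 0.841,
               tolerance = 0.05 / 0.841)
  # 4:1 rectangle: A = 4 w^2, P = 10 w
  expect_equal(circularity(measure_geometry(make_rect(160, 40), 1)), 0.503,
               tolerance = 0.05 / 0.503)
})

test_that("aspect ratio and extent follow their defining ratios", {
  g <- list(A = 50, P = 30, major = 4, minor = 2, bbox_area = 64)
  expect_equal(aspect_ratio(g), 2)
  expect_equal(extent(g), 50 / 64)

  expect_equal(aspect_ratio(measure_geometry(make_disk(40), 1)), 1,
               tolerance = 0.02)
  # axis-aligned ellipse fills pi/4 of its bounding box
  expect_equal(extent(measure_geometry(make_ellipse(40, 20), 1)), pi / 4,
               tolerance = 0.02 / (pi / 4))
  # rotation grows the bounding box, shrinking extent
  rot <- extent(measure_geometry(make_ellipse(40, 20, theta = pi / 4), 1))
  expect_lt(rot, pi / 4 - 0.02)
  # a filled rectangle is its own bounding box
  expect_equal(extent(measure_geometry(make_rect(60, 30), 1)), 1)
})

test_that("batch APIdx normalization: zero minimum, bounded maximum", {
  geoms <- list(list(A = 20, P = 10), list(A = 30, P = 10), list(A = 40, P = 10))
  expect_equal(api_index(geoms), c(0, 0.25, 0.5))

  same <- list(list(A = 10, P = 5), list(A = 10, P = 5))
  expect_equal(api_index(same), c(0, 0))

  set.seed(1)
  rand <- lapply(1:20, function(i) list(A = runif(1, 50, 500), P = runif(1, 20, 90)))
  idx <- api_index(rand)
  ap <- vapply(rand, function(g) g$A / g$P, numeric(1))
  expect_equal(min(idx), 0)
  expect_equal(max(idx), 1 - min(ap) / max(ap))
  expect_lt(max(idx), 1)

  expect_error(api_index(list(list(A = 1, P = 1))), "at least 2")
})

test_that("box-counting dimension: plane-filling, curve and grain ordering", {
  expect_equal(fractal_dimension(matrix(TRUE, 64, 64)), 2, tolerance = 0.025)
  line <- matrix(FALSE, 64, 64); line[32, ] <- TRUE
  expect_equal(fractal_dimension(line), 1, tolerance = 0.1)
  expect_error(fractal_dimension(matrix(c(TRUE, TRUE), 2, 2)), "too small")

  # bold short grains score higher than slender grains at fixed resolution
  bold <- render_grain_scene(the_specs[3], 10, seed = 41)     # BMB-like
  slender <- render_grain_scene(the_specs[7], 10, seed = 42)  # LGW-like
  fd_bold <- mean(extract_features(bold$image, label_grains(bold$image))$FD)
  fd_slender <- mean(extract_features(slender$image,
                                      label_grains(slender$image))$FD)
  expect_gt(fd_bold, fd_slender)
})

test_that("grain color averages CIELab over the mask", {
  labs <- matrix(0L, 8, 8); labs[3:6, 3:6] <- 1L
  white <- array(1, dim = c(8, 8, 3))
  col <- grain_color(white, labs, 1)
  expect_equal(unname(col["L"]), 100, tolerance = 0.001)
  expect_lt(abs(col["a"]), 0.01); expect_lt(abs(col["b"]), 0.01)

  black <- array(0, dim = c(8, 8, 3))
  expect_equal(unname(grain_color(black, labs, 1)["L"]), 0, tolerance = 1e-6)

  gray <- array(119 / 255, dim = c(8, 8, 3))
  colg <- grain_color(gray, labs, 1)
  expect_equal(unname(colg["L"]), 49.9, tolerance = 0.01)
  expect_lt(abs(colg["a"]), 0.5); expect_lt(abs(colg["b"]), 0.5)
})

test_that("yellowness index formula and its class-mean consistency", {
  expect_equal(yellowness_index(50, 0), 0)
  # evaluating the formula at class-mean L and b reproduces the catalogue's
  # per-grain-mean YI within 5% (mean-of-ratios vs ratio-of-means)
  kho <- yellowness_index(55.96, -1.61)
  expect_equal(kho, -4.11, tolerance = 0.002)
  expect_lt(abs(kho - (-4.17)) / 4.17, 0.05)
  wro <- yellowness_index(29.60, 4.19)
  expect_equal(wro, 20.22, tolerance = 0.001)
  expect_lt(abs(wro - 19.59) / 19.59, 0.05)
  expect_error(yellowness_index(0, 1), "L <= 0")
})

test_that("extract_features yields a complete, batch-normalized table", {
  sc <- render_grain_scene(the_specs[c(1, 9, 14)], 6, image_size = c(480, 640),
                           seed = 51)
  lr <- label_grains(sc$image)
  tab <- extract_features(sc$image, lr)
  expect_equal(nrow(tab), 18)
  expect_named(tab, c("grain_id", "FD", "Cir", "AR", "Ext", "APIdx",
                      "L", "a", "b", "YI"))
  expect_false(any(is.na(tab)))
  expect_equal(min(tab$APIdx), 0)
  expect_lt(max(tab$APIdx), 1)
  expect_equal(tab$YI, 142.86 * tab$b / tab$L)
  # descriptor domains
  expect_true(all(tab$Cir > 0))
  expect_true(all(tab$AR >= 1))
  expect_true(all(tab$Ext > 0 & tab$Ext <= 1))
  expect_true(all(tab$FD > 0.9 & tab$FD < 2.1))

  # empty labeling gives an empty table, not an error
  expect_equal(nrow(extract_features(sc$image,
                                     matrix(0L, dim(sc$image)[1],
                                            dim(sc$image)[2]))), 0)
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  expect_equal(read_feature_table(f)$AR, tab$AR, tolerance = 1e-12)
})

test_that("extracted color matches the rendered class color", {
  # BKR renders from Lab (27.54, 14.64, 4.97); recovery within 2 Lab units
  sc <- render_grain_scene(the_specs[14], 12, seed = 61)
  tab <- extract_features(sc$image, label_grains(sc$image))
  expect_equal(mean(tab$L), 27.54, tolerance = 2 / 27.54)
  expect_lt(abs(mean(tab$a) - 14.64), 2)
  expect_lt(abs(mean(tab$b) - 4.97), 2)
})

test_that("aspect-ratio shape classes separate bold, medium and slender", {
  # bold (< 2): KHO; medium (2.1-3): MOB; slender (> 3): BAS
  sc <- render_grain_scene(the_specs[c(1, 12, 9)], 8, image_size = c(520, 680),
                           seed = 71)
  lr <- label_grains(sc$image)
  tab <- extract_features(sc$image, lr)
  m <- match_truth(lr$labels, sc$truth)
  cls <- sc$truth$class_id
  expect_lt(mean(tab$AR[m][cls == 1]), 2)
  expect_gt(mean(tab$AR[m][cls == 12]), 2)
  expect_lt(mean(tab$AR[m][cls == 12]), 3)
  expect_gt(mean(tab$AR[m][cls == 9]), 3)
})
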