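# Morphometric feature panel: geometric oracles, intensity statistics,
# invariances.

test_that("uniform disk phantom yields the expected panel values", {
  d <- disk_mask(20, 64)
  img <- matrix(0, 64, 64); img[d == 1] <- 100
  fe <- extract_features(img, d)
  expect_named(fe, feature_names())
  expect_equal(unname(fe["solidity"]), 1, tolerance = 0.02)
  expect_equal(unname(fe["long_axis"]), 40, tolerance = 0.02 * 40)
  expect_equal(unname(fe["short_axis"]), 40, tolerance = 0.02 * 40)
  expect_equal(unname(fe["nodal_density"]), 100)
  expect_equal(unname(fe["heterogeneity"]), 0)
  expect_equal(unname(fe["area"]), sum(d))
  # checkerboard +/-10 texture: density unchanged, heterogeneity positive
  chk <- img
  chk[d == 1] <- 100 + 10 * (-1)^(row(img)[d == 1] + col(img)[d == 1])
  fe2 <- extract_features(chk, d)
  expect_equal(unname(fe2["nodal_density"]), mean(chk[d == 1]))
  expect_gt(unname(fe2["heterogeneity"]), 0)
})

test_that("axis diameters follow the moment formulas and are rotation-invariant", {
  rect <- matrix(0, 80, 100); rect[11:30, 21:80] <- 1 # 20 x 60
  ax <- axis_diameters(rect)
  expect_equal(unname(ax["long"] / ax["short"]), 3, tolerance = 0.05 * 3)
  # moment oracle for a w x h rectangle: axis = 4 * sqrt(side^2 / 12)
  expect_equal(unname(ax["long"]), 4 * sqrt(60^2 / 12), tolerance = 0.05 * 69)
  rot <- t(rect)
  expect_equal(unname(axis_diameters(rot)), unname(ax), tolerance = 0.01 * 69)
  # spacing scales linearly
  expect_equal(unname(axis_diameters(rect, spacing = 0.5)), unname(ax) / 2)
  expect_error(axis_diameters(matrix(c(1, rep(0, 8)), 3, 3)), "2 pixels")
})

test_that("solidity is 1 for convex masks and matches the brute-force hull oracle", {
  expect_equal(solidity(disk_mask(20, 64)), 1, tolerance = 0.02)
  rect <- matrix(0, 30, 30); rect[5:20, 8:25] <- 1
  expect_equal(solidity(rect), 1, tolerance = 0.02)
  # plus-sign pentomino vs brute-force point-in-hull count
  m <- matrix(0, 9, 9); m[5, 4:6] <- 1; m[4, 5] <- 1; m[6, 5] <- 1
  pts <- which(m == 1, arr.ind = TRUE)
  hullpoly <- cbind(pts[, 2], pts[, 1])[grDevices::chull(pts[, 2], pts[, 1]), ]
  cnt <- 0
  for (x in 1:9) for (y in 1:9) {
    on_hull <- any(abs(hullpoly[, 1] - x) < 1e-9 &
                   abs(hullpoly[, 2] - y) < 1e-9)
    if (on_hull || oracle_point_in_poly(x, y, hullpoly)) cnt <- cnt + 1
  }
  expect_equal(solidity(m), 5 / max(5, cnt))
  # spicule growth decreases solidity monotonically
  sols <- vapply(c(0.2, 0.5, 0.8), function(irr) {
    solidity(make_node_phantom(phantom_spec("spiculated", 40,
                                            irregularity = irr),
                               seed = 3)$mask)
  }, numeric(1))
  expect_true(all(diff(sols) < 0))
})

test_that("box-counting dimension: ~1 for smooth boundaries, ~log4/log3 for the Koch boundary", {
  expect_equal(fractal_dimension(disk_mask(50, 128)), 1, tolerance = 0.1)
  bar <- matrix(0, 64, 64); bar[30:34, 5:60] <- 1
  expect_equal(fractal_dimension(bar), 1, tolerance = 0.1)
  koch <- make_node_phantom(phantom_spec("koch_like", size_px = 160),
                            seed = 1, size = 320)
  expect_equal(fractal_dimension(koch$mask), log(4) / log(3),
               tolerance = 0.12)
  expect_error(fractal_dimension(matrix(c(1, rep(0, 63)), 8, 8)),
               "fewer than 8")
})

test_that("irregular phantoms have higher fractal dimension than smooth ones at equal area", {
  for (s in 1:10) {
    sm <- make_node_phantom(phantom_spec("disk", 40, irregularity = 0),
                            seed = s)
    ir <- make_node_phantom(phantom_spec("spiculated", 40,
                                         irregularity = 0.8), seed = s)
    expect_equal(sum(sm$mask), sum(ir$mask), tolerance = 0.1 * sum(sm$mask))
    expect_gt(fractal_dimension(ir$mask), fractal_dimension(sm$mask))
    expect_lt(solidity(ir$mask), solidity(sm$mask))
  }
})

test_that("intensity features match brute-force oracles", {
  set.seed(77)
  img <- matrix(rnorm(32 * 32, 120, 15), 32, 32)
  m <- disk_mask(10, 32)
  vals <- img[m == 1]
  expect_equal(nodal_density(img, m), sum(vals) / length(vals),
               tolerance = 1e-12)
  expect_equal(heterogeneity(img, m),
               sqrt(sum((vals - mean(vals))^2) / length(vals)),
               tolerance = 1e-10)
  # two-value region {0, 200} in equal proportion has SD 100
  img2 <- matrix(0, 32, 32)
  inside <- which(m == 1)
  img2[inside[seq_along(inside) %% 2 == 0]] <- 200
  img2[inside[seq_along(inside) %% 2 == 1]] <- 0
  if (length(inside) %% 2 == 1) img2[inside[1]] <- 100 # keep mean at 100
  expect_equal(nodal_density(img2, m), 100, tolerance = 1)
  expect_equal(heterogeneity(matrix(rep(c(0, 200), 8), 4, 4),
                             matrix(1, 4, 4)), 100)
  expect_equal(heterogeneity(img * 0 + 5, m), 0)
})

test_that("shape features ignore intensity offsets; intensity features ignore translation", {
  ph <- make_node_phantom(phantom_spec("spiculated", 36, irregularity = 0.5,
                                       heterogeneity_sd = 8), seed = 4)
  f1 <- extract_features(ph$image, ph$mask)
  f2 <- extract_features(ph$image + 55, ph$mask)
  shape <- c("area", "perimeter", "long_axis", "short_axis", "axis_ratio",
             "circularity", "eccentricity", "extent", "solidity",
             "compactness", "fractal_dimension", "boundary_irregularity",
             "radial_length_variance")
  expect_equal(f1[shape], f2[shape], tolerance = 1e-9)
  # rigid translation of image + mask leaves the intensity features
  # unchanged exactly, and everything else unchanged up to the box-grid
  # alignment of the fractal estimate
  shift <- function(m, k) rbind(matrix(0, k, ncol(m)),
                                m[1:(nrow(m) - k), ])
  f3 <- extract_features(shift(ph$image, 5), shift(ph$mask, 5))
  intensity <- c("nodal_density", "heterogeneity", "intensity_entropy",
                 "intensity_skewness", "intensity_kurtosis")
  expect_equal(f1[intensity], f3[intensity], tolerance = 1e-10)
  expect_equal(f1, f3, tolerance = 0.05)
})

test_that("size features scale correctly under phantom upscaling", {
  a <- make_node_phantom(phantom_spec("disk", 24), seed = 9)
  b <- make_node_phantom(phantom_spec("disk", 48), seed = 9)
  fa <- extract_features(a$image, a$mask)
  fb <- extract_features(b$image, b$mask)
  expect_equal(unname(fb["area"] / fa["area"]), 4, tolerance = 0.05 * 4)
  expect_equal(unname(fb["perimeter"] / fa["perimeter"]), 2,
               tolerance = 0.05 * 2)
  expect_equal(unname(fb["long_axis"] / fa["long_axis"]), 2,
               tolerance = 0.05 * 2)
})

test_that("degenerate masks raise data errors and border masks warn", {
  img <- matrix(1, 16, 16)
  expect_error(extract_features(img, matrix(0, 16, 16)), "empty")
  b <- matrix(0, 16, 16); b[1:6, 3:10] <- 1
  expect_warning(extract_features(img, b), "border")
})
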