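# Synthetic fixtures with exact ground truth: noisy piecewise-constant
# shape images, adjacent-object scenes, node phantoms with controllable
# boundary irregularity / internal heterogeneity, and labeled feature
# tables with a known informative subset. Every generator is a pure
# function of its spec and seed.

#' Phantom specification
#'
#' @param shape One of `"disk"`, `"ellipse"`, `"spiculated"`,
#'   `"koch_like"`.
#' @param size_px Nominal diameter in pixels (`>= 8`). The rendered region
#'   is area-normalised to the disk of this diameter, so phantoms differing
#'   only in `irregularity` have equal area.
#' @param irregularity Boundary perturbation amplitude in `[0, 1]`
#'   (0 = smooth convex outline).
#' @param base_intensity Mean intensity inside the region.
#' @param heterogeneity_sd SD of i.i.d. Gaussian texture added inside.
#' @param background_intensity Intensity outside the region.
#' @param center `(x, y)` placement on the canvas (`NULL` = canvas centre).
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("disk", "ellipse", "spiculated",
                                   "koch_like"),
                         size_px = 40, irregularity = 0,
                         base_intensity = 100, heterogeneity_sd = 0,
                         background_intensity = 0, center = NULL) {
  shape <- match.arg(shape)
  if (size_px < 8) stop("size_px must be >= 8", call. = FALSE)
  if (irregularity < 0 || irregularity > 1)
    stop("irregularity must be in [0, 1]", call. = FALSE)
  if (heterogeneity_sd < 0)
    stop("heterogeneity_sd must be non-negative", call. = FALSE)
  structure(list(shape = shape, size_px = size_px,
                 irregularity = irregularity,
                 base_intensity = base_intensity,
                 heterogeneity_sd = heterogeneity_sd,
                 background_intensity = background_intensity,
                 center = center),
            class = "phantom_spec")
}

# Closed boundary polygon of a phantom around `center`, area-normalised to
# pi * (size_px/2)^2. Uses the RNG stream of the caller.
phantom_polygon <- function(spec, center, n_vertices = 720) {
  r0 <- spec$size_px / 2
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[seq_len(n_vertices)]
  if (spec$shape == "koch_like") {
    poly <- koch_polygon(level = 4)
    poly <- poly * spec$size_px # unit construction scaled to nominal size
  } else {
    r <- switch(spec$shape,
      disk = rep(r0, n_vertices),
      ellipse = {
        a <- r0 * 1.3; b <- r0 / 1.3
        a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
      },
      spiculated = rep(r0, n_vertices))
    if (spec$irregularity > 0) {
      modes <- if (spec$shape == "spiculated") 8:14 else 3:7
      amp <- stats::runif(length(modes))
      phase <- stats::runif(length(modes), 0, 2 * pi)
      s <- colSums(amp * sin(outer(modes, th) + phase))
      s <- s / max(abs(s))
      bump <- if (spec$shape == "spiculated")
        abs(s)^0.5 * sign(s) else s
      r <- r * (1 + 0.35 * spec$irregularity * bump)
    }
    poly <- cbind(r * cos(th), r * sin(th))
  }
  # area-normalise, then place
  scale <- sqrt(pi * r0^2 / polygon_area(poly))
  poly <- poly * scale
  cbind(x = poly[, 1] + center[1], y = poly[, 2] + center[2])
}

# Koch snowflake boundary (triadic, given level), centred at origin with
# unit circumradius before scaling; returned as an (x, y) polygon.
koch_polygon <- function(level = 4) {
  p <- rbind(c(cos(pi / 2), sin(pi / 2)),
             c(cos(pi / 2 + 2 * pi / 3), sin(pi / 2 + 2 * pi / 3)),
             c(cos(pi / 2 + 4 * pi / 3), sin(pi / 2 + 4 * pi / 3))) * 0.5
  for (l in seq_len(level)) {
    n <- nrow(p)
    nxt <- p[c(2:n, 1), , drop = FALSE]
    a <- p
    b <- p + (nxt - p) / 3
    d <- p + 2 * (nxt - p) / 3
    seg <- nxt - p
    # outward bump: rotate the middle third by -60 degrees
    rot <- cbind(seg[, 1] / 3 * cos(-pi / 3) - seg[, 2] / 3 * sin(-pi / 3),
                 seg[, 1] / 3 * sin(-pi / 3) + seg[, 2] / 3 * cos(-pi / 3))
    cpt <- b + rot
    out <- matrix(0, 4 * n, 2)
    out[seq(1, 4 * n, by = 4), ] <- a
    out[seq(2, 4 * n, by = 4), ] <- b
    out[seq(3, 4 * n, by = 4), ] <- cpt
    out[seq(4, 4 * n, by = 4), ] <- d
    p <- out
  }
  p
}

# Rasterise a polygon on an nr x nc grid (pixel centres, even-odd rule).
rasterize_polygon <- function(poly, nr, nc) {
  px <- rep(seq_len(nc), each = nr)
  py <- rep(seq_len(nr), times = nc)
  matrix(as.numeric(points_in_polygon(px, py, poly)), nr, nc)
}

#' Render a multi-shape test image with exact ground truth
#'
#' Draws the given phantoms on a constant background, adds each phantom's
#' internal Gaussian texture, and returns the clean image together with the
#' per-shape ground-truth masks and the exact boundary edge map (the
#' 8-connected inner boundaries of the masks).
#'
#' @param width,height Canvas size in pixels.
#' @param shapes List of [phantom_spec()] objects, each with a `center`.
#' @param seed Integer seed (texture randomness only).
#' @return List with `image`, `masks` (list of 0/1 matrices),
#'   `true_edges` (0/1 matrix).
#' @export
make_shapes_image <- function(width, height, shapes, seed = 1) {
  if (inherits(shapes, "phantom_spec")) shapes <- list(shapes)
  with_seed(seed, {
    img <- matrix(shapes[[1]]$background_intensity, height, width)
    masks <- vector("list", length(shapes))
    occupied <- matrix(0, height, width)
    for (i in seq_along(shapes)) {
      sp <- shapes[[i]]
      ctr <- if (is.null(sp$center)) c(width / 2, height / 2) else sp$center
      poly <- phantom_polygon(sp, ctr)
      if (any(poly[, 1] < 1) || any(poly[, 1] > width) ||
          any(poly[, 2] < 1) || any(poly[, 2] > height))
        stop("shape ", i, " does not fit in the canvas", call. = FALSE)
      m <- rasterize_polygon(poly, height, width)
      if (any(m * occupied == 1))
        stop("shape ", i, " overlaps an earlier shape", call. = FALSE)
      occupied <- occupied + m
      masks[[i]] <- m
      inside <- m == 1
      img[inside] <- sp$base_intensity +
        if (sp$heterogeneity_sd > 0)
          stats::rnorm(sum(inside), 0, sp$heterogeneity_sd) else 0
    }
    edges <- matrix(0, height, width)
    for (m in masks) edges[boundary_pixels(m) == 1] <- 1
    list(image = img, masks = masks, true_edges = edges)
  })
}

#' Corrupt an image with Gaussian noise at a target SNR
#'
#' Adds zero-mean i.i.d. Gaussian noise with variance
#' `var(image) / 10^(snr_db / 10)`, so [compute_snr_db()] of the pair
#' recovers `snr_db` up to sampling error (within about 0.1 dB for images
#' of 128 x 128 and larger).
#'
#' @param image Numeric matrix with positive variance.
#' @param snr_db Target signal-to-noise ratio in dB; `Inf` returns the
#'   image unchanged.
#' @param seed Integer seed.
#' @return Noisy matrix of the same shape.
#' @export
add_gaussian_noise <- function(image, snr_db, seed = 1) {
  v <- stats::var(as.vector(image))
  if (v == 0) stop("constant image: SNR undefined", call. = FALSE)
  if (is.infinite(snr_db) && snr_db > 0) return(image)
  sd_noise <- sqrt(v / 10^(snr_db / 10))
  with_seed(seed,
    image + matrix(stats::rnorm(length(image), 0, sd_noise),
                   nrow(image), ncol(image)))
}

#' Scene of two closely adjacent objects
#'
#' Builds the adjacency stress test for segmentation: a target disk and a
#' larger, higher-contrast distractor disk separated by `gap_px` at their
#' closest approach. The stronger distractor edge dominates the gradient
#' field in the gap, which is exactly the situation where a plain GVF
#' snake leaks onto the neighbour and the repulsive force is needed.
#'
#' @param gap_px Edge-to-edge separation in pixels (`>= 1`).
#' @param seed Integer seed (reserved; the scene is piecewise constant).
#' @param size Canvas side length.
#' @return List with `image`, `target_mask`, `distractor_mask`,
#'   `target_center`, `target_radius`.
#' @export
make_adjacent_objects_scene <- function(gap_px = 2, seed = 1, size = 128) {
  if (gap_px < 1) stop("gap_px must be >= 1", call. = FALSE)
  r_t <- 18; r_d <- 24
  cx_t <- 40; cy <- size / 2
  cx_d <- cx_t + r_t + gap_px + r_d
  if (cx_d + r_d > size - 2)
    stop("gap_px too large for the canvas", call. = FALSE)
  xs <- matrix(rep(seq_len(size), each = size), size, size)
  ys <- matrix(rep(seq_len(size), times = size), size, size)
  target <- matrix(as.numeric((xs - cx_t)^2 + (ys - cy)^2 <= r_t^2),
                   size, size)
  distractor <- matrix(as.numeric((xs - cx_d)^2 + (ys - cy)^2 <= r_d^2),
                       size, size)
  if (any(target * distractor == 1))
    stop("gap_px forces overlap", call. = FALSE)
  # low-contrast target beside a high-contrast neighbour: the regime where
  # the neighbour's stronger edges dominate the gradient field in the gap
  img <- matrix(0, size, size)
  img[target == 1] <- 70
  img[distractor == 1] <- 255
  list(image = img, target_mask = target, distractor_mask = distractor,
       target_center = c(cx_t, cy), target_radius = r_t)
}

#' Node phantom with controlled morphology
#'
#' Renders one node on a square canvas: the boundary is a radially
#' perturbed closed curve whose perturbation amplitude grows with
#' `spec$irregularity`, and the interior intensity is
#' `base_intensity + N(0, heterogeneity_sd)`. The returned mask is the
#' exact generating region. Emulates the smooth-to-spiculated morphology
#' axis that separates benign from malignant nodes.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @param size Canvas side length (`NULL`: sized to fit the phantom).
#' @return List with `image` and `mask`.
#' @export
make_node_phantom <- function(spec, seed = 1, size = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(size)) size <- ceiling(spec$size_px * 2.2)
  ctr <- if (is.null(spec$center)) c(size / 2, size / 2) else spec$center
  with_seed(seed, {
    poly <- phantom_polygon(spec, ctr)
    mask <- rasterize_polygon(poly, size, size)
    img <- matrix(spec$background_intensity, size, size)
    inside <- mask == 1
    img[inside] <- spec$base_intensity +
      if (spec$heterogeneity_sd > 0)
        stats::rnorm(sum(inside), 0, spec$heterogeneity_sd) else 0
    list(image = img, mask = mask)
  })
}

#' Table specification for labeled feature data
#'
#' @param n_samples Number of samples (`>= 10`).
#' @param n_features Number of feature columns (default 19).
#' @param informative Indices of informative features.
#' @param effect_size Per-class mean shift of each informative feature
#'   (class means at `+/- effect_size / 2`, unit variance).
#' @param class_balance Probability of the `+1` (malignant) class.
#' @param seed Integer seed.
#' @return List of class `table_spec`.
#' @export
table_spec <- function(n_samples = 200, n_features = 19,
                       informative = 1:3, effect_size = 2,
                       class_balance = 0.5, seed = 1) {
  if (n_samples < 10) stop("n_samples must be >= 10", call. = FALSE)
  if (length(informative) > 0 &&
      (min(informative) < 1 || max(informative) > n_features))
    stop("informative indices out of range", call. = FALSE)
  if (class_balance <= 0 || class_balance >= 1)
    stop("class_balance must be in (0, 1)", call. = FALSE)
  structure(list(n_samples = n_samples, n_features = n_features,
                 informative = informative, effect_size = effect_size,
                 class_balance = class_balance, seed = seed),
            class = "table_spec")
}

#' Generate a labeled feature table with a known informative subset
#'
#' Labels are drawn `+1` with probability `class_balance` (re-drawn until
#' both classes appear). Informative columns are `N(y * effect_size / 2,
#' 1)`; all other columns are pure `N(0, 1)` noise.
#'
#' @param spec A [table_spec()].
#' @return A [labeled_data()] with columns `f01`, `f02`, ...
#' @export
make_feature_dataset <- function(spec) {
  stopifnot(inherits(spec, "table_spec"))
  with_seed(spec$seed, {
    repeat {
      y <- sample(c(1, -1), spec$n_samples, replace = TRUE,
                  prob = c(spec$class_balance, 1 - spec$class_balance))
      if (length(unique(y)) == 2) break
    }
    x <- matrix(stats::rnorm(spec$n_samples * spec$n_features),
                spec$n_samples, spec$n_features)
    eff <- rep_len(spec$effect_size, length(spec$informative))
    for (k in seq_along(spec$informative))
      x[, spec$informative[k]] <- x[, spec$informative[k]] +
        y * eff[k] / 2
    colnames(x) <- sprintf("f%02d", seq_len(spec$n_features))
    labeled_data(x, y)
  })
}

#' Morphometric feature table from rendered node phantoms
#'
#' End-to-end synthetic analogue of a clinical feature table: renders `n`
#' node phantoms and runs [extract_features()] on each, so all 19 panel
#' features are measured, informative and incidental alike. Each phantom
#' draws its parameters from class-conditional distributions that overlap
#' — benign (`-1`) nodes are smoother and more homogeneous on average,
#' malignant (`+1`) ones more irregular and heterogeneous, while size and
#' mean attenuation are class-independent — so the classes are genuinely
#' confusable, as clinical benign/malignant nodes are.
#'
#' @param n Number of phantoms (split evenly between classes).
#' @param seed Integer seed.
#' @return A [labeled_data()] whose columns are [feature_names()].
#' @export
make_phantom_dataset <- function(n = 100, seed = 1) {
  y <- rep(c(-1, 1), length.out = n)
  x <- matrix(NA_real_, n, 19, dimnames = list(NULL, feature_names()))
  for (i in seq_len(n)) {
    sp <- with_seed(seed + 7919L * i, {
      if (y[i] == 1)
        phantom_spec(sample(c("spiculated", "disk"), 1, prob = c(0.7, 0.3)),
                     size_px = stats::runif(1, 28, 52),
                     irregularity = stats::runif(1, 0.15, 0.6),
                     base_intensity = stats::runif(1, 90, 110),
                     heterogeneity_sd = stats::runif(1, 6, 16))
      else
        phantom_spec(sample(c("disk", "ellipse"), 1),
                     size_px = stats::runif(1, 28, 52),
                     irregularity = stats::runif(1, 0, 0.35),
                     base_intensity = stats::runif(1, 90, 110),
                     heterogeneity_sd = stats::runif(1, 2, 10))
    })
    ph <- make_node_phantom(sp, seed = seed + i)
    x[i, ] <- extract_features(ph$image, ph$mask)
  }
  labeled_data(x, y)
}
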