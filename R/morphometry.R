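# Morphometric feature panel for a segmented node: shape descriptors from
# the binary mask, intensity statistics from the underlying image. The set
# of 19 named features is a fixed, order-stable contract of the package.
# The identity of the original clinical 19-feature panel is not public; this
# list is the package's reconstruction of a standard morphology + histogram
# panel, and it contains all seven measurements reported as discriminative
# (fractal dimension, heterogeneity, long-/short-axis diameter, nodal
# density, solidity).

#' Canonical feature names
#'
#' The ordered names of the 19-element feature vector returned by
#' [extract_features()].
#'
#' @return Character vector of length 19.
#' @export
feature_names <- function() {
  c("area", "perimeter", "long_axis", "short_axis", "axis_ratio",
    "circularity", "eccentricity", "extent", "solidity", "compactness",
    "fractal_dimension", "boundary_irregularity", "nodal_density",
    "heterogeneity", "intensity_entropy", "intensity_skewness",
    "intensity_kurtosis", "edge_sharpness", "radial_length_variance")
}

# Inner boundary pixels: mask pixels with at least one background pixel
# (or the image border) among their 8 neighbours. Returns a 0/1 matrix.
boundary_pixels <- function(mask) {
  padded <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  core <- function(m) m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
  nb_min <- pmin(core(shift_n(padded)), core(shift_s(padded)),
                 core(shift_w(padded)), core(shift_e(padded)),
                 core(shift_n(shift_w(padded))), core(shift_n(shift_e(padded))),
                 core(shift_s(shift_w(padded))), core(shift_s(shift_e(padded))))
  out <- matrix(0, nrow(mask), ncol(mask))
  out[mask == 1 & nb_min == 0] <- 1
  out
}

# Ordered boundary chain via EBImage; falls back to unordered boundary
# pixels only for degenerate regions. Returns (x, y) matrix.
trace_boundary <- function(mask) {
  oc <- EBImage::ocontour(mask)
  if (length(oc) == 0) stop("mask has no traceable boundary", call. = FALSE)
  longest <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  # ocontour is 0-based (row, col) in EBImage's x=row convention; EBImage
  # images transpose display but store [x, y] = [row, col] of the matrix.
  # Convert to this package's (x = col, y = row), 1-based.
  cbind(x = longest[, 2] + 1, y = longest[, 1] + 1)
}

# Perimeter as the length of the closed 8-connected boundary chain.
mask_perimeter <- function(mask) {
  p <- trace_boundary(mask)
  if (nrow(p) < 2) return(0)
  q <- rbind(p, p[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(q)^2)))
}

#' Long- and short-axis diameters
#'
#' Axis lengths of the ellipse with the same second-order central moments
#' as the mask: `4 * sqrt(eigenvalue)` of the pixel-coordinate covariance,
#' scaled by `spacing`. For a disk of radius r both equal `2 r`.
#'
#' @param mask Binary 0/1 matrix with at least 2 set pixels.
#' @param spacing Physical units per pixel (mm); 1 reports pixels.
#' @return Named vector `c(long, short)`.
#' @export
axis_diameters <- function(mask, spacing = 1) {
  check_mask(mask)
  pts <- which(mask == 1, arr.ind = TRUE)
  if (nrow(pts) < 2) stop("mask must contain at least 2 pixels", call. = FALSE)
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  # population covariance of pixel centre coordinates
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  cv <- crossprod(d) / nrow(pts)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  c(long = 4 * sqrt(ev[1]) * spacing, short = 4 * sqrt(ev[2]) * spacing)
}

#' Solidity
#'
#' Region area divided by the area of its convex hull, both measured by
#' counting pixel centres (the hull area counts pixel centres inside or on
#' the hull polygon of the mask's pixel centres). 1 for convex regions,
#' smaller for spiculated or lobulated ones.
#'
#' @param mask Binary 0/1 matrix (non-empty).
#' @return Solidity in `(0, 1]`.
#' @export
solidity <- function(mask) {
  check_mask(mask)
  npix <- sum(mask)
  if (npix == 0) stop("mask is empty", call. = FALSE)
  hull_px <- convex_hull_pixels(mask)
  npix / max(npix, sum(hull_px))
}

# Rasterised convex hull: pixels whose centres are inside or on the convex
# hull polygon of the mask's pixel centres. Always a superset of the mask.
convex_hull_pixels <- function(mask) {
  pts <- which(mask == 1, arr.ind = TRUE) # (row, col)
  xy <- cbind(pts[, 2], pts[, 1])
  h <- grDevices::chull(xy)
  poly <- xy[h, , drop = FALSE]
  out <- mask
  if (nrow(poly) < 3) return(out)
  nr <- nrow(mask); nc <- ncol(mask)
  px <- rep(seq_len(nc), each = nr)
  py <- rep(seq_len(nr), times = nc)
  inside <- points_in_polygon(px, py, poly) # boundary centres included
  out[matrix(inside, nr, nc)] <- 1
  out
}

#' Box-counting fractal dimension of a region boundary
#'
#' Covers the 8-connected inner boundary pixel set with grids of dyadic box
#' sizes (2, 4, ... up to a quarter of the smaller image side) and returns
#' the least-squares slope of `log N(eps)` against `log(1/eps)`, clipped to
#' `[1, 2]`. Near 1 for smooth (rectifiable) outlines, larger for
#' irregular, space-filling ones.
#'
#' @param mask Binary 0/1 matrix whose boundary has at least 8 pixels.
#' @return Estimated dimension in `[1, 2]`.
#' @export
fractal_dimension <- function(mask) {
  check_mask(mask)
  bp <- which(boundary_pixels(mask) == 1, arr.ind = TRUE)
  if (nrow(bp) < 8)
    stop("boundary has fewer than 8 pixels; dimension undefined",
         call. = FALSE)
  max_box <- min(nrow(mask), ncol(mask)) / 4
  sizes <- 2^(1:floor(log2(max_box)))
  if (length(sizes) < 2)
    stop("image too small for a box-size range", call. = FALSE)
  counts <- vapply(sizes, function(s) {
    nrow(unique(cbind(ceiling(bp[, 1] / s), ceiling(bp[, 2] / s))))
  }, numeric(1))
  fit <- stats::lm(log(counts) ~ log(1 / sizes))
  min(2, max(1, unname(stats::coef(fit)[2])))
}

#' Mean intensity inside the node (nodal density)
#'
#' Arithmetic mean of image intensities over mask pixels — the CT
#' attenuation analogue.
#'
#' @param image Numeric matrix.
#' @param mask Binary 0/1 matrix of the same shape (non-empty).
#' @return Mean intensity.
#' @export
nodal_density <- function(image, mask) {
  check_mask(mask)
  if (!all(dim(image) == dim(mask)))
    stop("image and mask must have the same shape", call. = FALSE)
  if (sum(mask) == 0) stop("mask is empty", call. = FALSE)
  mean(image[mask == 1])
}

#' Intensity heterogeneity inside the node
#'
#' Population standard deviation of intensities over mask pixels, a proxy
#' for internal structure (necrosis, mixed tissue). The companion entropy
#' feature in the full panel captures the histogram shape.
#'
#' @inheritParams nodal_density
#' @return Population SD (0 for a uniform region).
#' @export
heterogeneity <- function(image, mask) {
  check_mask(mask)
  if (!all(dim(image) == dim(mask)))
    stop("image and mask must have the same shape", call. = FALSE)
  vals <- image[mask == 1]
  if (length(vals) < 2) stop("mask must contain at least 2 pixels",
                             call. = FALSE)
  sqrt(mean((vals - mean(vals))^2))
}

# Shannon entropy (bits) of the 32-bin histogram of intensities.
intensity_entropy <- function(vals, n_bins = 32) {
  if (max(vals) == min(vals)) return(0)
  cuts <- seq(min(vals), max(vals), length.out = n_bins + 1)
  p <- tabulate(findInterval(vals, cuts, rightmost.closed = TRUE),
                nbins = n_bins)
  p <- p[p > 0] / length(vals)
  -sum(p * log2(p))
}

#' Extract the 19-feature morphometric vector
#'
#' Computes the full ordered panel named by [feature_names()] for one
#' segmented node: size and shape descriptors (areas/lengths scaled by
#' `spacing` and `spacing^2`), boundary complexity (box-counting fractal
#' dimension, irregularity), and intensity statistics inside the mask.
#' Deterministic in its inputs.
#'
#' @param image Numeric matrix.
#' @param mask Binary 0/1 matrix of the same shape (non-empty).
#' @param spacing Physical units per pixel (mm); 1 reports pixel units.
#' @return Named numeric vector of length 19.
#' @export
extract_features <- function(image, mask, spacing = 1) {
  check_image(image); check_mask(mask)
  if (!all(dim(image) == dim(mask)))
    stop("image and mask must have the same shape", call. = FALSE)
  npix <- sum(mask)
  if (npix == 0) stop("mask is empty", call. = FALSE)
  pts <- which(mask == 1, arr.ind = TRUE)
  if (any(pts[, 1] %in% c(1, nrow(mask))) ||
      any(pts[, 2] %in% c(1, ncol(mask))))
    warning("mask touches the image border; features may be truncated")

  area <- npix * spacing^2
  per <- mask_perimeter(mask) * spacing
  ax <- axis_diameters(mask, spacing)
  axis_ratio <- unname(ax["long"] / max(ax["short"], .Machine$double.eps))
  circularity <- if (per > 0) 4 * pi * area / per^2 else NA_real_
  ecc <- if (ax["long"] > 0)
    sqrt(max(0, 1 - (ax["short"] / ax["long"])^2)) else 0
  bbox <- (diff(range(pts[, 1])) + 1) * (diff(range(pts[, 2])) + 1)
  extent <- npix / bbox
  sol <- solidity(mask)
  compact <- if (area > 0) per^2 / (4 * pi * area) else NA_real_
  fd <- fractal_dimension(mask)
  hull_per <- convex_perimeter(mask) * spacing
  irregularity <- if (hull_per > 0) per / hull_per else NA_real_

  vals <- image[mask == 1]
  dens <- mean(vals)
  het <- sqrt(mean((vals - dens)^2))
  ent <- intensity_entropy(vals)
  skw <- if (het > 0) e1071::skewness(vals, type = 1) else 0
  krt <- if (het > 0) e1071::kurtosis(vals, type = 1) else 0

  gm <- grad_mag(image)
  bp <- boundary_pixels(mask)
  sharp <- mean(gm[bp == 1]) / max(spacing, .Machine$double.eps)

  bxy <- which(bp == 1, arr.ind = TRUE)
  ctr <- colMeans(pts)
  rad <- sqrt((bxy[, 1] - ctr[1])^2 + (bxy[, 2] - ctr[2])^2)
  nrl <- if (mean(rad) > 0) mean((rad - mean(rad))^2) / mean(rad)^2 else 0

  out <- c(area, per, unname(ax["long"]), unname(ax["short"]), axis_ratio,
           circularity, ecc, extent, sol, compact, fd, irregularity,
           dens, het, ent, skw, krt, sharp, nrl)
  names(out) <- feature_names()
  out
}

# Perimeter of the convex hull polygon of the mask's pixel centres.
convex_perimeter <- function(mask) {
  pts <- which(mask == 1, arr.ind = TRUE)
  xy <- cbind(pts[, 2], pts[, 1])
  h <- grDevices::chull(xy)
  poly <- xy[h, , drop = FALSE]
  if (nrow(poly) < 2) return(0)
  q <- rbind(poly, poly[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(q)^2)))
}
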