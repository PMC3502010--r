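# Canny edge extraction and edge-map quality measures used to evaluate how
# well a denoiser preserves boundaries.

#' Canny edge detection
#'
#' Standard Canny pipeline: Gaussian smoothing at scale `sigma`, Sobel
#' gradient, non-maximum suppression along the quantised gradient
#' direction, and double-threshold hysteresis (8-connected): weak edge
#' pixels (`>= low`) are kept only when their component contains a strong
#' pixel (`>= high`).
#'
#' @param image Numeric matrix.
#' @param low,high Hysteresis thresholds on gradient magnitude,
#'   `0 <= low < high`.
#' @param sigma Positive smoothing scale (pixels).
#' @return Binary 0/1 matrix of edge pixels.
#' @export
canny_edges <- function(image, low, high, sigma = 1) {
  check_image(image)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (low < 0 || low >= high)
    stop("thresholds must satisfy 0 <= low < high", call. = FALSE)
  s <- gaussian_smooth(image, sigma)
  # Sobel
  gx <- shift_e(s) - shift_w(s) +
    (shift_n(shift_e(s)) - shift_n(shift_w(s)) +
     shift_s(shift_e(s)) - shift_s(shift_w(s))) / 2
  gy <- shift_s(s) - shift_n(s) +
    (shift_w(shift_s(s)) - shift_w(shift_n(s)) +
     shift_e(shift_s(s)) - shift_e(shift_n(s))) / 2
  mag <- sqrt(gx^2 + gy^2)
  # Non-maximum suppression with direction quantised to 0/45/90/135 deg.
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4
  nb1 <- mag; nb2 <- mag
  h <- sector == 0          # gradient ~horizontal -> compare east/west
  v <- sector == 2          # gradient ~vertical -> compare north/south
  d1 <- sector == 1         # diagonal (+x,+y)
  d2 <- sector == 3         # diagonal (+x,-y)
  e <- shift_e(mag); w <- shift_w(mag); n <- shift_n(mag); so <- shift_s(mag)
  se <- shift_s(shift_e(mag)); nw <- shift_n(shift_w(mag))
  ne <- shift_n(shift_e(mag)); sw <- shift_s(shift_w(mag))
  nb1[h] <- e[h];  nb2[h] <- w[h]
  nb1[v] <- so[v]; nb2[v] <- n[v]
  nb1[d1] <- se[d1]; nb2[d1] <- nw[d1]
  nb1[d2] <- ne[d2]; nb2[d2] <- sw[d2]
  keep <- mag >= nb1 & mag >= nb2
  weak <- keep & mag >= low
  strong <- keep & mag >= high
  if (!any(strong)) return(matrix(0, nrow(image), ncol(image)))
  lab <- label_components8(matrix(as.numeric(weak), nrow(weak)))
  good <- unique(lab[strong])
  out <- matrix(0, nrow(image), ncol(image))
  out[lab %in% good[good > 0]] <- 1
  out
}

#' Automatic Canny thresholds
#'
#' Convenience rule: `high` is the given quantile of the non-zero gradient
#' magnitudes of the smoothed image and `low = 0.4 * high`.
#'
#' @param image Numeric matrix.
#' @param sigma Smoothing scale passed to the gradient.
#' @param q Quantile for the high threshold.
#' @return List with `low` and `high`.
#' @export
canny_auto_thresholds <- function(image, sigma = 1, q = 0.9) {
  mag <- grad_mag(gaussian_smooth(image, sigma))
  pos <- mag[mag > 0]
  if (length(pos) == 0) return(list(low = 0.1, high = 0.25))
  high <- as.numeric(stats::quantile(pos, q))
  list(low = 0.4 * high, high = high)
}

#' Count 8-connected components of a binary map
#'
#' @param edges Binary 0/1 matrix.
#' @return Integer number of 8-connected components.
#' @export
count_edge_components <- function(edges) {
  max(label_components8(edges))
}

#' Boundary F1 score with pixel tolerance
#'
#' Compares a predicted edge map with a ground-truth one: a predicted pixel
#' counts as correct when a true edge pixel lies within `tol_px` (Euclidean
#' distance), and a true pixel as recalled when a predicted pixel lies
#' within `tol_px`. Returns the harmonic mean of the two rates.
#'
#' @param predicted,truth Binary 0/1 matrices of identical shape.
#' @param tol_px Matching tolerance in pixels.
#' @return List with `precision`, `recall`, `f1` (0 when either map is empty).
#' @export
boundary_f1 <- function(predicted, truth, tol_px = 1) {
  check_mask(predicted); check_mask(truth)
  if (!all(dim(predicted) == dim(truth)))
    stop("edge maps must have the same shape", call. = FALSE)
  if (sum(predicted) == 0 || sum(truth) == 0)
    return(list(precision = 0, recall = 0, f1 = 0))
  # distmap gives distance to the nearest zero pixel, so feed 1 - map
  d_truth <- as.matrix(EBImage::distmap(1 - truth))
  d_pred <- as.matrix(EBImage::distmap(1 - predicted))
  precision <- mean(d_truth[predicted == 1] <= tol_px)
  recall <- mean(d_pred[truth == 1] <= tol_px)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}
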