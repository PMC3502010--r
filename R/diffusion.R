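# Nonlinear diffusion denoising. Images are plain numeric matrices
# (rows = y, columns = x), processed as real values.

#' Diffusion parameters
#'
#' Bundles the parameters shared by the PDE denoisers. `mu_diff` trades
#' smoothing against the adaptive fidelity term of the edge-enhanced model,
#' `sigma0` is the scale (in pixels) of the Gaussian used to regularise the
#' gradient fed to the diffusivity, and `contrast_k` is the diffusivity
#' contrast parameter; when `NULL` it is set per image to the 90th
#' percentile of the smoothed gradient magnitude at the first iteration.
#'
#' @param mu_diff Non-negative smoothing/fidelity trade-off weight.
#' @param sigma0 Positive Gaussian scale (pixels) for gradient regularisation.
#' @param contrast_k Positive diffusivity contrast parameter, or `NULL` to
#'   choose it from the image (90th percentile of `|grad(G_sigma0 * I)|`).
#' @param time_step Explicit Euler step; must be `<= 0.25` for stability of
#'   the 2-D explicit scheme.
#' @param n_iterations Number of explicit steps (`>= 1`).
#' @param epsilon Degeneracy guard added to denominators.
#' @param g Diffusivity family: `"perona_malik"` for `1/(1 + (s/k)^2)` or
#'   `"tv"` for `1/(s + epsilon)`.
#' @return A list of class `diffusion_params`.
#' @export
diffusion_params <- function(mu_diff = 1.0, sigma0 = 1.0, contrast_k = NULL,
                             time_step = 0.2, n_iterations = 50,
                             epsilon = 1e-12,
                             g = c("perona_malik", "tv")) {
  g <- match.arg(g)
  if (mu_diff < 0) stop("mu_diff must be non-negative", call. = FALSE)
  if (sigma0 <= 0) stop("sigma0 must be positive", call. = FALSE)
  if (!is.null(contrast_k) && contrast_k <= 0)
    stop("contrast_k must be positive", call. = FALSE)
  if (time_step <= 0 || time_step > 0.25)
    stop("time_step must be in (0, 0.25] for the explicit scheme",
         call. = FALSE)
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  structure(list(mu_diff = mu_diff, sigma0 = sigma0, contrast_k = contrast_k,
                 time_step = time_step, n_iterations = n_iterations,
                 epsilon = epsilon, g = g),
            class = "diffusion_params")
}

#' Gaussian smoothing with reflective boundary
#'
#' Convolves an image with a normalised 2-D Gaussian kernel of scale
#' `sigma0`, realised as two separable 1-D passes. The kernel radius is
#' `ceiling(3 * sigma0)`; when that rounds to zero the image is returned
#' unchanged. Boundaries are handled by symmetric reflection, so constant
#' images are exact fixed points.
#'
#' @param image Numeric matrix.
#' @param sigma0 Positive Gaussian scale in pixels.
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(image, sigma0) {
  if (!is.numeric(sigma0) || length(sigma0) != 1 || sigma0 <= 0)
    stop("sigma0 must be a positive scalar", call. = FALSE)
  check_image(image, min_dim = 1L)
  r <- ceiling(3 * sigma0)
  if (r < 1) return(image)
  k <- exp(-(-r:r)^2 / (2 * sigma0^2))
  k <- k / sum(k)
  conv_reflect(conv_reflect(image, k, along = "rows"), k, along = "cols")
}

# 1-D convolution along rows (vertical) or cols (horizontal) with symmetric
# reflection at the borders: index i < 1 maps to 1 - i, i > n to 2n + 1 - i.
conv_reflect <- function(m, k, along = c("rows", "cols")) {
  along <- match.arg(along)
  r <- (length(k) - 1L) %/% 2L
  n <- if (along == "rows") nrow(m) else ncol(m)
  out <- matrix(0, nrow(m), ncol(m))
  for (o in -r:r) {
    idx <- seq_len(n) + o
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    out <- out + k[o + r + 1L] *
      (if (along == "rows") m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
  }
  out
}

#' Edge-stopping diffusivity
#'
#' The scalar diffusivity `g(s)` controlling how strongly smoothing acts at
#' gradient magnitude `s`: close to 1 in flat regions, decaying towards 0 at
#' strong edges. Two families are provided: the rational Perona-Malik form
#' `1/(1 + (s/k)^2)` (default) and the total-variation form
#' `1/(s + epsilon)` capped at 1.
#'
#' @param gradient_magnitude Non-negative scalar, vector or matrix.
#' @param contrast_k Positive contrast parameter.
#' @param g Diffusivity family, `"perona_malik"` or `"tv"`.
#' @param epsilon Degeneracy guard for the TV form.
#' @return Values in `(0, 1]`, same shape as `gradient_magnitude`.
#' @export
diffusivity <- function(gradient_magnitude, contrast_k,
                        g = c("perona_malik", "tv"), epsilon = 1e-12) {
  g <- match.arg(g)
  if (any(gradient_magnitude < 0))
    stop("gradient_magnitude must be non-negative", call. = FALSE)
  if (contrast_k <= 0) stop("contrast_k must be positive", call. = FALSE)
  if (g == "perona_malik") {
    1 / (1 + (gradient_magnitude / contrast_k)^2)
  } else {
    pmin(1, 1 / (gradient_magnitude + epsilon))
  }
}

# Resolve contrast_k: explicit value, or the 90th percentile of the
# regularised gradient magnitude of the initial image.
resolve_contrast_k <- function(image, params) {
  if (!is.null(params$contrast_k)) return(params$contrast_k)
  gm <- grad_mag(gaussian_smooth(image, params$sigma0))
  k <- as.numeric(stats::quantile(gm, 0.9))
  if (k <= 0) k <- 1 # constant image: any k, diffusion vanishes anyway
  k
}

#' Edge-enhanced nonlinear diffusion
#'
#' Evolves `u_t = mu * div(g(|grad(G_sigma0 * u)|) grad u)
#' - (|grad u| / max|grad u|) (u - I)` from `u = I` by explicit Euler steps
#' with no-flux boundary. The fidelity weight `|grad u| / max|grad u|` is
#' recomputed each iteration; near edges it pins `u` to the observed image,
#' while in homogeneous regions diffusion dominates and removes noise. When
#' `max|grad u| = 0` (constant image) the weight is defined as 0.
#'
#' @param image Numeric matrix (the observed image `I`).
#' @param params A [diffusion_params()] object.
#' @return Denoised matrix of the same shape.
#' @export
edge_enhanced_diffusion <- function(image, params = diffusion_params()) {
  check_image(image)
  stopifnot(inherits(params, "diffusion_params"))
  k <- resolve_contrast_k(image, params)
  u <- image
  for (it in seq_len(params$n_iterations)) {
    g <- diffusivity(grad_mag(gaussian_smooth(u, params$sigma0)), k,
                     g = params$g, epsilon = params$epsilon)
    gm <- grad_mag(u)
    m <- max(gm)
    w <- if (m > 0) gm / (m + params$epsilon) else 0
    u <- u + params$time_step *
      (params$mu_diff * flux_divergence(u, g) - w * (u - image))
  }
  if (!all(is.finite(u)))
    stop("diffusion diverged: non-finite values (reduce time_step)",
         call. = FALSE)
  u
}

#' Perona-Malik anisotropic diffusion
#'
#' Baseline scheme `u_t = div(g(|grad u|) grad u)`: no fidelity term and no
#' Gaussian regularisation of the gradient driving the diffusivity. With
#' no-flux boundary the image mean is conserved and the output obeys the
#' discrete maximum principle.
#'
#' @inheritParams edge_enhanced_diffusion
#' @return Denoised matrix of the same shape.
#' @export
perona_malik <- function(image, params = diffusion_params()) {
  check_image(image)
  stopifnot(inherits(params, "diffusion_params"))
  k <- resolve_contrast_k(image, params)
  u <- image
  for (it in seq_len(params$n_iterations)) {
    g <- diffusivity(grad_mag(u), k, g = params$g, epsilon = params$epsilon)
    u <- u + params$time_step * flux_divergence(u, g)
  }
  if (!all(is.finite(u)))
    stop("diffusion diverged: non-finite values (reduce time_step)",
         call. = FALSE)
  u
}

#' Total-variation (Rudin-Osher-Fatemi) denoising
#'
#' Explicit gradient descent on the TV functional with quadratic fidelity:
#' `u_t = div(grad u / (|grad u| + epsilon)) - lambda_fid (u - I)`. The
#' `epsilon`-regularised diffusivity is evaluated at cell centres and
#' averaged onto the half grid by the conservative divergence stencil.
#'
#' @inheritParams edge_enhanced_diffusion
#' @param lambda_fid Positive fidelity weight; large values keep the output
#'   close to the input.
#' @param epsilon Regularisation of `1/|grad u|`; this numerical guard is
#'   deliberately larger than the `diffusion_params` degeneracy guard so the
#'   explicit step remains stable.
#' @return Denoised matrix of the same shape.
#' @export
tv_rof <- function(image, lambda_fid = 0.1, params = diffusion_params(),
                   epsilon = 1e-2) {
  check_image(image)
  stopifnot(inherits(params, "diffusion_params"))
  if (lambda_fid <= 0) stop("lambda_fid must be positive", call. = FALSE)
  u <- image
  for (it in seq_len(params$n_iterations)) {
    g <- 1 / (grad_mag(u) + epsilon)
    # stability clamp: dt * 4 * max(g) <= 1 for the diffusion part and
    # dt * lambda_fid <= 1 for the explicit fidelity part
    dt <- min(params$time_step, 0.25 / max(g), 1 / lambda_fid)
    u <- u + dt * (flux_divergence(u, g) - lambda_fid * (u - image))
  }
  if (!all(is.finite(u)))
    stop("TV iteration diverged: non-finite values (reduce time_step)",
         call. = FALSE)
  u
}

#' Median filter
#'
#' Replaces each pixel by the exact median of its `size x size`
#' neighbourhood (reflected boundary).
#'
#' @param image Numeric matrix.
#' @param size Odd window side length, `>= 3`.
#' @return Filtered matrix of the same shape.
#' @export
median_filter <- function(image, size = 3L) {
  check_image(image)
  if (size %% 2 != 1 || size < 3)
    stop("size must be an odd integer >= 3", call. = FALSE)
  r <- (size - 1L) %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  ridx <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  stack <- matrix(0, nr * nc, size * size)
  k <- 0L
  for (dy in -r:r) {
    iy <- ridx(seq_len(nr) + dy, nr)
    for (dx in -r:r) {
      ix <- ridx(seq_len(nc) + dx, nc)
      k <- k + 1L
      stack[, k] <- image[iy, ix]
    }
  }
  # row-wise exact median via a partial sort over the window columns
  sorted <- apply(stack, 1L, sort.int, method = "quick")
  mid <- (size * size + 1L) / 2L
  matrix(sorted[mid, ], nr, nc)
}

#' Bilateral filter
#'
#' Edge-preserving weighted average: each output pixel averages its spatial
#' neighbours with weights that decay both with spatial distance
#' (`sigma_space`) and with intensity difference (`sigma_range`), so
#' averaging does not cross strong edges. As `sigma_range` grows the filter
#' tends to plain Gaussian smoothing.
#'
#' @param image Numeric matrix.
#' @param sigma_space Positive spatial scale (pixels).
#' @param sigma_range Positive intensity scale.
#' @return Filtered matrix; output values stay within the input range.
#' @export
bilateral_filter <- function(image, sigma_space = 2, sigma_range = 25) {
  check_image(image)
  if (sigma_space <= 0 || sigma_range <= 0)
    stop("sigma_space and sigma_range must be positive", call. = FALSE)
  r <- ceiling(3 * sigma_space)
  nr <- nrow(image); nc <- ncol(image)
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  ridx <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  for (dy in -r:r) {
    iy <- ridx(seq_len(nr) + dy, nr)
    for (dx in -r:r) {
      ix <- ridx(seq_len(nc) + dx, nc)
      nb <- image[iy, ix, drop = FALSE]
      w <- exp(-(dx^2 + dy^2) / (2 * sigma_space^2)) *
        exp(-(nb - image)^2 / (2 * sigma_range^2))
      num <- num + w * nb
      den <- den + w
    }
  }
  num / den
}

#' Signal-to-noise ratio in decibels
#'
#' `10 log10(var(clean) / var(noisy - clean))`, the variance-ratio SNR used
#' to state the corruption level of synthetic test images. Returns `Inf`
#' when the two images are identical (zero noise variance).
#'
#' @param clean,noisy Numeric matrices of identical shape.
#' @return SNR in dB (possibly `Inf`).
#' @export
compute_snr_db <- function(clean, noisy) {
  if (!all(dim(clean) == dim(noisy)))
    stop("clean and noisy must have the same shape", call. = FALSE)
  vs <- stats::var(as.vector(clean))
  if (vs == 0) stop("clean image has zero variance; SNR undefined",
                    call. = FALSE)
  vn <- stats::var(as.vector(noisy - clean))
  if (vn == 0) return(Inf)
  10 * log10(vs / vn)
}
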