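# Gradient vector flow (GVF) external force field and the repulsive
# modification that keeps a snake from leaking onto adjacent objects.

#' Edge force map
#'
#' The scalar edge map driving the external force: `f = |grad(G_sigma0 * I)|^2`,
#' the squared gradient magnitude of the Gaussian-smoothed image. Large on
#' boundaries, zero in flat regions, invariant to adding a constant to the
#' image.
#'
#' @param image Numeric matrix.
#' @param sigma0 Positive smoothing scale (pixels).
#' @return Non-negative matrix of the same shape.
#' @export
edge_force_map <- function(image, sigma0 = 1) {
  check_image(image)
  s <- gaussian_smooth(image, sigma0)
  grad_x(s)^2 + grad_y(s)^2
}

#' Solve the gradient vector flow equations
#'
#' Computes the GVF field `v = (u, v)` as the fixed point of the coupled
#' Euler equations `mu lap(u) - (fx^2 + fy^2)(u - fx) = 0` (and likewise
#' for `v` with `fy`), discretised with the 4-neighbour Laplacian and
#' replicated boundary. Solved by explicit relaxation from `(fx, fy)`; the
#' diffusion term extends the gradient of the edge map far into homogeneous
#' regions, which is what gives the snake its large capture range.
#'
#' @param f Edge map (non-negative matrix), e.g. from [edge_force_map()].
#' @param mu_gvf Positive regularisation weight; larger values give a
#'   smoother, farther-reaching field.
#' @param n_iter Number of relaxation sweeps.
#' @return List of class `vector_field` with matrices `u` (x-component)
#'   and `v` (y-component).
#' @export
solve_gvf <- function(f, mu_gvf = 0.2, n_iter = 200) {
  check_image(f, min_dim = 3L)
  if (mu_gvf <= 0) stop("mu_gvf must be positive", call. = FALSE)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  fx <- grad_x(f); fy <- grad_y(f)
  b <- fx^2 + fy^2
  # Explicit step: stable when dt*mu <= 1/4 and dt*max(b) <= 1.
  dt <- min(0.25 / mu_gvf, if (max(b) > 0) 1 / max(b) else Inf, 1)
  u <- fx; v <- fy
  lap <- function(m) shift_n(m) + shift_s(m) + shift_w(m) + shift_e(m) - 4 * m
  for (i in seq_len(n_iter)) {
    u <- u + dt * (mu_gvf * lap(u) - b * (u - fx))
    v <- v + dt * (mu_gvf * lap(v) - b * (v - fy))
  }
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("GVF relaxation diverged: non-finite field values", call. = FALSE)
  structure(list(u = u, v = v), class = "vector_field")
}

#' Apply the repulsive force outside the initialisation region
#'
#' Modifies an external force field so that a snake initialised inside
#' region `R` is repelled from structures outside it: vectors at pixels
#' inside `R` are kept, vectors outside `R` are negated
#' (`v- = v` if in `R`, `-v` otherwise). Negation reverses the pull of
#' neighbouring objects' edges, so an adjacent structure pushes the curve
#' back towards its legitimate boundary instead of capturing it. The
#' operation preserves vector magnitude everywhere and is an involution on
#' the outside region.
#'
#' @param field A `vector_field` (list with matrices `u`, `v`).
#' @param region Binary 0/1 matrix, 1 inside the initialisation region.
#' @return A `vector_field` of the same shape.
#' @export
apply_repulsion <- function(field, region) {
  check_mask(region)
  if (!all(dim(field$u) == dim(region)))
    stop("field and region must have the same shape", call. = FALSE)
  sgn <- ifelse(region == 1, 1, -1)
  structure(list(u = field$u * sgn, v = field$v * sgn),
            class = "vector_field")
}
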