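# Parametric active contour (snake): semi-implicit evolution under internal
# tension/rigidity forces and an external force field sampled bilinearly.
# Contours are 2-column (x, y) matrices of subpixel coordinates, implicitly
# closed; x runs along columns, y along rows, pixel centres at integer
# coordinates (1-based).

#' Snake parameters
#'
#' @param alpha Non-negative tension (first-derivative) weight.
#' @param beta Non-negative rigidity (second-derivative) weight.
#' @param lambda_ext Positive weight of the external force.
#' @param gamma Positive evolution step size.
#' @param mu_gvf Positive GVF regularisation weight (used when the caller
#'   builds the field; recorded here so one object configures a run).
#' @param gvf_iterations GVF relaxation sweeps.
#' @param evolve_iterations Maximum snake iterations.
#' @param convergence_tol Stop when the largest point displacement in one
#'   step falls below this (pixels).
#' @param normalize_force Use unit-normalised external vectors instead of
#'   raw GVF magnitudes.
#' @param resample_every Re-distribute points to uniform arc spacing every
#'   this many iterations.
#' @return A list of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.1, beta = 0.1, lambda_ext = 1.0,
                         gamma = 1.0, mu_gvf = 0.2, gvf_iterations = 200,
                         evolve_iterations = 400, convergence_tol = 0.05,
                         normalize_force = FALSE, resample_every = 10) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  if (lambda_ext <= 0 || gamma <= 0 || mu_gvf <= 0 || convergence_tol <= 0)
    stop("lambda_ext, gamma, mu_gvf, convergence_tol must be > 0",
         call. = FALSE)
  if (gvf_iterations < 1 || evolve_iterations < 1)
    stop("iteration counts must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, lambda_ext = lambda_ext,
                 gamma = gamma, mu_gvf = mu_gvf,
                 gvf_iterations = gvf_iterations,
                 evolve_iterations = evolve_iterations,
                 convergence_tol = convergence_tol,
                 normalize_force = normalize_force,
                 resample_every = resample_every),
            class = "snake_params")
}

#' Circular initial contour
#'
#' @param center Numeric `(x, y)` pair.
#' @param radius Positive radius in pixels.
#' @param n_points Number of vertices, `>= 8`.
#' @return A 2-column `(x, y)` matrix (closed implicitly).
#' @export
initialize_contour <- function(center, radius, n_points = 100) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (n_points < 8) stop("n_points must be >= 8", call. = FALSE)
  th <- seq(0, 2 * pi, length.out = n_points + 1)[seq_len(n_points)]
  cbind(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}

# Resample a closed contour to n points at uniform arc spacing.
resample_contour <- function(p, n = nrow(p)) {
  q <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(q)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(p)
  target <- seq(0, total, length.out = n + 1)[seq_len(n)]
  cbind(x = stats::approx(s, q[, 1], xout = target)$y,
        y = stats::approx(s, q[, 2], xout = target)$y)
}

# Bilinear sample of a matrix at subpixel (x, y); x indexes columns,
# y rows, clamped to the grid.
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  dx <- x - x0; dy <- y - y0
  m[cbind(y0, x0)] * (1 - dx) * (1 - dy) +
    m[cbind(y0, x0 + 1)] * dx * (1 - dy) +
    m[cbind(y0 + 1, x0)] * (1 - dx) * dy +
    m[cbind(y0 + 1, x0 + 1)] * dx * dy
}

#' Evolve a snake in an external force field
#'
#' Minimises the snake energy (tension `alpha |C'|^2`, rigidity
#' `beta |C''|^2`, external term weighted by `lambda_ext`) by the standard
#' semi-implicit scheme: internal forces are treated implicitly through a
#' cyclic banded system solved once per point count, the external force
#' explicitly by bilinear sampling of the field at the current vertices.
#' Points are re-distributed to uniform arc spacing every
#' `resample_every` iterations; evolution stops when the largest vertex
#' displacement drops below `convergence_tol` or after
#' `evolve_iterations` steps.
#'
#' @param init 2-column `(x, y)` contour matrix within the field grid.
#' @param field A `vector_field` from [solve_gvf()] (optionally passed
#'   through [apply_repulsion()]).
#' @param params A [snake_params()] object.
#' @return The final contour (same number of points), with attributes
#'   `iterations` and `converged`.
#' @export
evolve_snake <- function(init, field, params = snake_params()) {
  if (!is.matrix(init) || ncol(init) != 2 || nrow(init) < 8)
    stop("init must be an (x, y) matrix with >= 8 points", call. = FALSE)
  stopifnot(inherits(params, "snake_params"))
  nr <- nrow(field$u); nc <- ncol(field$u)
  n <- nrow(init)

  # Internal force matrix: A = (I + gamma * (alpha*K2 + beta*K4)) with K2 the
  # cyclic negative second difference and K4 the cyclic fourth difference.
  circ <- function(coefs) {
    m <- matrix(0, n, n)
    offs <- seq_along(coefs) - (length(coefs) + 1L) %/% 2L
    for (i in seq_len(n)) for (k in seq_along(coefs)) {
      j <- ((i - 1 + offs[k]) %% n) + 1
      m[i, j] <- m[i, j] + coefs[k]
    }
    m
  }
  K2 <- circ(c(-1, 2, -1))
  K4 <- circ(c(1, -4, 6, -4, 1))
  A <- diag(n) + params$gamma * (params$alpha * K2 + params$beta * K4)
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("singular internal-force system (degenerate parameters)",
         call. = FALSE))

  p <- init
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(params$evolve_iterations)) {
    iters <- it
    fx <- bilinear_sample(field$u, p[, 1], p[, 2])
    fy <- bilinear_sample(field$v, p[, 1], p[, 2])
    if (params$normalize_force) {
      mag <- sqrt(fx^2 + fy^2)
      nz <- mag > 1e-12
      fx[nz] <- fx[nz] / mag[nz]; fy[nz] <- fy[nz] / mag[nz]
      fx[!nz] <- 0; fy[!nz] <- 0
    }
    newx <- Ainv %*% (p[, 1] + params$gamma * params$lambda_ext * fx)
    newy <- Ainv %*% (p[, 2] + params$gamma * params$lambda_ext * fy)
    newp <- cbind(x = as.vector(newx), y = as.vector(newy))
    if (any(newp[, 1] < 0.5) || any(newp[, 1] > nc + 0.5) ||
        any(newp[, 2] < 0.5) || any(newp[, 2] > nr + 0.5)) {
      err <- simpleError("contour escaped the field grid during evolution")
      err$last_contour <- p
      stop(err)
    }
    disp <- max(sqrt(rowSums((newp - p)^2)))
    p <- newp
    if (it %% params$resample_every == 0) p <- resample_contour(p, n)
    if (disp < params$convergence_tol) { converged <- TRUE; break }
  }
  p <- resample_contour(p, n)
  attr(p, "iterations") <- iters
  attr(p, "converged") <- converged
  p
}

#' Rasterise a closed contour to a binary mask
#'
#' Marks the pixels whose centres lie inside the closed polygon (even-odd
#' rule). Vertices outside the grid are allowed; the polygon is evaluated
#' as-is and only in-grid pixel centres are tested (effectively clipping),
#' with a warning.
#'
#' @param contour 2-column `(x, y)` matrix.
#' @param shape `(rows, cols)` of the output mask.
#' @return Binary 0/1 matrix.
#' @export
contour_to_mask <- function(contour, shape) {
  nr <- shape[1]; nc <- shape[2]
  if (any(contour[, 1] < 0.5) || any(contour[, 1] > nc + 0.5) ||
      any(contour[, 2] < 0.5) || any(contour[, 2] > nr + 0.5))
    warning("contour extends outside the grid; mask is clipped")
  px <- rep(seq_len(nc), each = nr)
  py <- rep(seq_len(nr), times = nc)
  inside <- points_in_polygon(px, py, contour)
  matrix(as.numeric(inside), nr, nc)
}

#' Dice overlap coefficient
#'
#' `2 |A & B| / (|A| + |B|)` between two binary masks.
#'
#' @param a,b Binary 0/1 matrices of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  check_mask(a); check_mask(b)
  if (!all(dim(a) == dim(b)))
    stop("masks must have the same shape", call. = FALSE)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a * b) / denom
}

#' Segment an object with the repulsive GVF snake
#'
#' Convenience wrapper chaining the full segmentation stage:
#' [edge_force_map()] on the (already denoised) image, [solve_gvf()],
#' optional [apply_repulsion()] with the region enclosed by the initial
#' contour, and [evolve_snake()].
#'
#' @param image Denoised numeric matrix.
#' @param init Initial contour (2-column matrix), e.g. from
#'   [initialize_contour()].
#' @param params A [snake_params()] object.
#' @param repulsive Apply the repulsive force outside the initial region.
#' @param sigma0 Smoothing scale for the edge force map.
#' @return List with `contour`, `mask`, and the `field` used.
#' @export
segment_node <- function(image, init, params = snake_params(),
                         repulsive = TRUE, sigma0 = 1) {
  f <- edge_force_map(image, sigma0)
  # GVF is linear in f; normalising the edge map to [0, 1] puts the
  # external force on the same unit scale for any image contrast
  if (max(f) > 0) f <- f / max(f)
  field <- solve_gvf(f, mu_gvf = params$mu_gvf,
                     n_iter = params$gvf_iterations)
  if (repulsive) {
    region <- contour_to_mask(init, dim(image))
    field <- apply_repulsion(field, region)
  }
  contour <- evolve_snake(init, field, params)
  list(contour = contour, mask = contour_to_mask(contour, dim(image)),
       field = field)
}
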