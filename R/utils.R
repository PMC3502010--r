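# Internal helpers shared across modules: neighbour shifts with replicated
# boundary (realising homogeneous Neumann no-flux conditions), central
# gradients, seeded RNG scoping, and validation.

# Neighbour copies with edge replication. "n" = row above, "s" = row below,
# "w" = column left, "e" = column right.
shift_n <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
shift_s <- function(m) m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
shift_w <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
shift_e <- function(m) m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE]

# Central-difference gradient; x runs along columns, y along rows.
# Replicated boundary makes the one-sided boundary derivative 0.5*(edge diff).
grad_x <- function(m) (shift_e(m) - shift_w(m)) / 2
grad_y <- function(m) (shift_s(m) - shift_n(m)) / 2

grad_mag <- function(m) sqrt(grad_x(m)^2 + grad_y(m)^2)

# Conservative divergence of g * grad(u) with diffusivity averaged to the
# half-grid: flux between a cell and each 4-neighbour uses the mean of the
# two cell diffusivities, so pairwise fluxes cancel exactly (mass
# conservation) and vanish across the replicated boundary (no flux).
flux_divergence <- function(u, g) {
  (g + shift_n(g)) / 2 * (shift_n(u) - u) +
  (g + shift_s(g)) / 2 * (shift_s(u) - u) +
  (g + shift_w(g)) / 2 * (shift_w(u) - u) +
  (g + shift_e(g)) / 2 * (shift_e(u) - u)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_image <- function(image, min_dim = 3L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(image)))
    stop("image contains non-finite pixels", call. = FALSE)
  if (nrow(image) < min_dim || ncol(image) < min_dim)
    stop("image must be at least ", min_dim, "x", min_dim, call. = FALSE)
  invisible(image)
}

check_mask <- function(mask) {
  if (!is.matrix(mask))
    stop("mask must be a matrix", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1", call. = FALSE)
  invisible(mask)
}

# 8-connected labeling of a binary matrix by iterative minimum-label
# propagation (EBImage::bwlabel is 4-connected). Exact; cost is one pass of
# 8 shifted pmin's per propagation sweep until a fixed point.
label_components8 <- function(mask) {
  check_mask(mask)
  lab <- matrix(0, nrow(mask), ncol(mask))
  on <- mask == 1
  lab[on] <- seq_len(sum(on))
  if (!any(on)) return(lab)
  big <- sum(on) + 1
  repeat {
    l <- lab
    l[!on] <- big
    nb <- pmin(shift_n(l), shift_s(l), shift_w(l), shift_e(l),
               shift_n(shift_w(l)), shift_n(shift_e(l)),
               shift_s(shift_w(l)), shift_s(shift_e(l)))
    new_lab <- pmin(l, nb)
    new_lab[!on] <- 0
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  # compact labels to 1..k
  ids <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], ids)
  lab
}

# Shoelace area of a closed polygon given as a 2-column (x, y) matrix.
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# Even-odd (ray crossing) test of grid points against a closed polygon.
# px, py are equal-length coordinate vectors; polygon rows are (x, y).
# Points lying exactly on a polygon edge count as inside.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  boundary <- logical(length(px))
  xs <- poly[, 1]; ys <- poly[, 2]
  scale <- max(abs(poly), 1)
  eps <- 1e-9 * scale
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    ex <- xs[j] - xs[i]; ey <- ys[j] - ys[i]
    len2 <- ex^2 + ey^2
    if (len2 > 0) {
      cross <- ex * (py - ys[i]) - ey * (px - xs[i])
      dot <- ex * (px - xs[i]) + ey * (py - ys[i])
      boundary <- boundary |
        (abs(cross) <= eps * sqrt(len2) & dot >= -eps & dot <= len2 + eps)
    } else {
      boundary <- boundary |
        (abs(px - xs[i]) <= eps & abs(py - ys[i]) <= eps)
    }
    j <- i
  }
  inside | boundary
}
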