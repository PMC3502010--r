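# Independent loop-based oracles for the PDE and geometry operations.
# Deliberately written with explicit per-pixel loops and direct index
# clamping, sharing no code with the package internals.

# replicate-boundary index
.clamp <- function(i, n) pmin(pmax(i, 1L), n)

# symmetric-reflection index
.reflect <- function(i, n) {
  i <- ifelse(i < 1L, 1L - i, i)
  ifelse(i > n, 2L * n + 1L - i, i)
}

# direct 2-D convolution with a normalised Gaussian kernel, reflection
oracle_gauss <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  if (r < 1) return(m)
  off <- -r:r
  k2 <- outer(exp(-off^2 / (2 * sigma^2)), exp(-off^2 / (2 * sigma^2)))
  k2 <- k2 / sum(k2)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in off) for (b in off) {
      acc <- acc + k2[a + r + 1, b + r + 1] *
        m[.reflect(i + a, nr), .reflect(j + b, nc)]
    }
    out[i, j] <- acc
  }
  out
}

# central gradient magnitude with replicated boundary, per pixel
oracle_grad_mag <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    gx <- (m[i, .clamp(j + 1L, nc)] - m[i, .clamp(j - 1L, nc)]) / 2
    gy <- (m[.clamp(i + 1L, nr), j] - m[.clamp(i - 1L, nr), j]) / 2
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

# one explicit Euler step of the edge-enhanced diffusion:
# u1 = u + dt * (mu * div(g grad u) - (|grad u|/max|grad u|) (u - I)),
# conservative half-grid fluxes, diffusivity g = 1/(1 + (s/k)^2) driven by
# the Gaussian-regularised gradient.
oracle_eed_step <- function(u, I, mu, sigma0, k, dt, eps = 1e-12) {
  nr <- nrow(u); nc <- ncol(u)
  gs <- oracle_grad_mag(oracle_gauss(u, sigma0))
  g <- 1 / (1 + (gs / k)^2)
  gm <- oracle_grad_mag(u)
  M <- max(gm)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    flux <- 0
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      qi <- .clamp(i + d[1], nr); qj <- .clamp(j + d[2], nc)
      flux <- flux + (g[i, j] + g[qi, qj]) / 2 * (u[qi, qj] - u[i, j])
    }
    w <- if (M > 0) gm[i, j] / (M + eps) else 0
    out[i, j] <- u[i, j] + dt * (mu * flux - w * (u[i, j] - I[i, j]))
  }
  out
}

# Jacobi iteration for the GVF Euler equations, run to a tight fixed point
oracle_jacobi_gvf <- function(f, mu, tol = 1e-13, maxit = 2e5) {
  nr <- nrow(f); nc <- ncol(f)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    gx[i, j] <- (f[i, .clamp(j + 1L, nc)] - f[i, .clamp(j - 1L, nc)]) / 2
    gy[i, j] <- (f[.clamp(i + 1L, nr), j] - f[.clamp(i - 1L, nr), j]) / 2
  }
  b <- gx^2 + gy^2
  u <- gx; v <- gy
  for (it in seq_len(maxit)) {
    un <- u; vn <- v
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      nbu <- u[.clamp(i - 1L, nr), j] + u[.clamp(i + 1L, nr), j] +
        u[i, .clamp(j - 1L, nc)] + u[i, .clamp(j + 1L, nc)]
      nbv <- v[.clamp(i - 1L, nr), j] + v[.clamp(i + 1L, nr), j] +
        v[i, .clamp(j - 1L, nc)] + v[i, .clamp(j + 1L, nc)]
      un[i, j] <- (mu * nbu + b[i, j] * gx[i, j]) / (4 * mu + b[i, j])
      vn[i, j] <- (mu * nbv + b[i, j] * gy[i, j]) / (4 * mu + b[i, j])
    }
    d <- max(abs(un - u), abs(vn - v))
    u <- un; v <- vn
    if (d < tol) break
  }
  list(u = u, v = v)
}

# shoelace polygon area
oracle_polygon_area <- function(p) {
  n <- nrow(p); j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# winding-number point-in-polygon (angle summation), independent of the
# package's ray-crossing implementation; undefined exactly on the boundary
oracle_point_in_poly <- function(px, py, poly) {
  ang <- 0
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(poly[i, 2] - py, poly[i, 1] - px)
    a2 <- atan2(poly[j, 2] - py, poly[j, 1] - px)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    ang <- ang + d
  }
  abs(ang) > pi
}

# binary disk mask helper
disk_mask <- function(r, size, cx = size / 2, cy = size / 2) {
  xs <- matrix(rep(seq_len(size), each = size), size, size)
  ys <- matrix(rep(seq_len(size), times = size), size, size)
  matrix(as.numeric((xs - cx)^2 + (ys - cy)^2 <= r^2), size, size)
}

# the shapes image used across the denoising/edge tests (Fig.-3-style)
standard_shapes_scene <- function(seed = 7) {
  make_shapes_image(128, 128, list(
    phantom_spec("disk", size_px = 36, base_intensity = 120,
                 center = c(36, 40)),
    phantom_spec("ellipse", size_px = 40, base_intensity = 200,
                 center = c(90, 44)),
    phantom_spec("disk", size_px = 30, base_intensity = 70,
                 center = c(60, 95))), seed = seed)
}
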