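# Nonlinear diffusion denoisers: kernel contracts, PDE scheme correctness,
# conservation/maximum principles, and denoising efficacy on noisy scenes.

test_that("gaussian_smooth is normalised, identity-limited and matches the discrete kernel", {
  const <- matrix(7, 9, 9)
  expect_equal(gaussian_smooth(const, 1.5), const, tolerance = 1e-12)

  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- gaussian_smooth(imp, 1)
  expect_equal(sm[11, 11], oracle_gauss(imp, 1)[11, 11], tolerance = 1e-12)
  # discrete normalised kernel centre is close to the continuous density
  expect_equal(sm[11, 11], 1 / (2 * pi), tolerance = 0.01)

  tiny <- matrix(rnorm(25), 5, 5)
  expect_identical(gaussian_smooth(tiny, 0.1), tiny) # radius rounds to 0

  expect_error(gaussian_smooth(const, 0), "positive")
  expect_error(gaussian_smooth(const, -1), "positive")
})

test_that("diffusivity is in (0,1], 1 at zero, 0.5 at s = k, and non-increasing", {
  expect_equal(diffusivity(0, 3), 1)
  expect_equal(diffusivity(2.5, 2.5), 0.5)
  s <- seq(0, 50, length.out = 200)
  for (k in c(0.5, 5, 40)) {
    g <- diffusivity(s, k)
    expect_true(all(g > 0 & g <= 1))
    expect_true(all(diff(g) <= 0))
  }
  gtv <- diffusivity(s, 1, g = "tv")
  expect_true(all(gtv > 0 & gtv <= 1))
  expect_true(all(diff(gtv) <= 0))
  expect_error(diffusivity(-1, 1), "non-negative")
})

test_that("one explicit edge-enhanced diffusion step matches the finite-difference oracle", {
  set.seed(21)
  u <- matrix(rnorm(25, 100, 20), 5, 5)
  params <- diffusion_params(mu_diff = 1.3, sigma0 = 0.8, contrast_k = 10,
                             time_step = 0.2, n_iterations = 1)
  got <- edge_enhanced_diffusion(u, params)
  want <- oracle_eed_step(u, u, mu = 1.3, sigma0 = 0.8, k = 10, dt = 0.2)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("constant images are fixed points of all five denoisers", {
  const <- matrix(42, 16, 16)
  p <- diffusion_params(n_iterations = 10)
  expect_equal(edge_enhanced_diffusion(const, p), const, tolerance = 1e-9)
  expect_equal(perona_malik(const, p), const, tolerance = 1e-9)
  expect_equal(tv_rof(const, 0.1, p), const, tolerance = 1e-9)
  expect_equal(median_filter(const, 3), const, tolerance = 1e-9)
  expect_equal(bilateral_filter(const, 2, 10), const, tolerance = 1e-9)
})

test_that("perona_malik conserves the mean and obeys the maximum principle", {
  sc <- standard_shapes_scene()
  noisy <- add_gaussian_noise(sc$image, 9.46, seed = 11)
  pm <- perona_malik(noisy, diffusion_params(n_iterations = 100))
  expect_equal(mean(pm), mean(noisy), tolerance = 1e-6)
  expect_gte(min(pm), min(noisy) - 1e-9)
  expect_lte(max(pm), max(noisy) + 1e-9)
  # noise variance within a true flat region strictly decreases
  flat <- sc$masks[[1]] == 1
  expect_lt(var(pm[flat]), var(noisy[flat]))
})

test_that("edge-enhanced diffusion denoises while keeping the step edge sharper than Perona-Malik", {
  step <- matrix(0, 64, 64); step[, 33:64] <- 100
  noisy <- add_gaussian_noise(step, 9.46, seed = 5)
  p <- diffusion_params(n_iterations = 50)
  eed <- edge_enhanced_diffusion(noisy, p)
  pm <- perona_malik(noisy, p)
  expect_gt(compute_snr_db(step, eed), compute_snr_db(step, noisy))
  jump <- function(m) mean(abs(m[, 33] - m[, 32]))
  expect_gte(jump(eed), jump(pm))
})

test_that("tv_rof reduces total variation and respects the strong-fidelity limit", {
  sc <- standard_shapes_scene()
  noisy <- add_gaussian_noise(sc$image, 9.46, seed = 11)
  tvar <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  out <- tv_rof(noisy, 0.1, diffusion_params(n_iterations = 100))
  expect_lt(tvar(out), tvar(noisy))
  hi <- tv_rof(noisy, 1000, diffusion_params())
  lo <- tv_rof(noisy, 1, diffusion_params())
  expect_lt(max(abs(hi - noisy)), max(abs(lo - noisy)))
})

test_that("median filter rejects impulses and follows the definition", {
  z <- matrix(0, 9, 9); z[5, 5] <- 100
  expect_equal(median_filter(z, 3), matrix(0, 9, 9), tolerance = 1e-9)
  patch <- matrix(1:9, 3, 3, byrow = TRUE)
  expect_equal(median_filter(patch, 3)[2, 2], 5, tolerance = 1e-9)
  expect_error(median_filter(z, 4), "odd")
})

test_that("bilateral filter keeps range, approaches Gaussian smoothing as sigma_range grows, and preserves a high step", {
  step <- matrix(0, 32, 32); step[, 17:32] <- 1000
  noisy <- add_gaussian_noise(step, 15, seed = 3)
  bl <- bilateral_filter(noisy, 2, 25)
  expect_gte(min(bl), min(noisy)); expect_lte(max(bl), max(noisy))
  expect_equal(bilateral_filter(noisy, 2, 1e12),
               gaussian_smooth(noisy, 2), tolerance = 1e-6)
  # step midline profile essentially unchanged, flat-region noise reduced
  expect_equal(mean(bl[, 17] - bl[, 16]), mean(noisy[, 17] - noisy[, 16]),
               tolerance = 0.1 * 1000)
  expect_lt(var(as.vector(bl[, 1:14])), var(as.vector(noisy[, 1:14])))
  expect_error(bilateral_filter(step, -1, 1), "positive")
})

test_that("compute_snr_db follows the variance-ratio definition", {
  set.seed(8)
  clean <- matrix(rnorm(256, 0, 10), 16, 16)
  expect_identical(compute_snr_db(clean, clean), Inf)
  noise <- matrix(rnorm(256, 0, sd(as.vector(clean))), 16, 16)
  noise <- noise * sd(as.vector(clean)) / sd(as.vector(noise))
  expect_equal(compute_snr_db(clean, clean + noise), 0, tolerance = 1e-9)
  expect_error(compute_snr_db(matrix(1, 4, 4), matrix(2, 4, 4)),
               "variance")
})
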