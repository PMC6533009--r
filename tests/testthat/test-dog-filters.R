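test_that("normalizing amplitudes follow the 2D Gaussian pdf normalizer", {
  p <- dog_params("isotropic-2", sigma1 = 1, sigma2 = 2)
  w <- normalizing_amplitude(p)
  expect_equal(w[["w1"]], 1 / (2 * pi), tolerance = 1e-12)
  expect_equal(w[["w2"]], 1 / (2 * pi * 4), tolerance = 1e-12)
  # a single rendered Gaussian with this amplitude sums to ~1 on a wide grid
  g <- oracle_gaussian_iso(w[["w1"]], 1, 15)
  expect_equal(sum(g), 1, tolerance = 1e-3)
  # anisotropic with sigma_x = sigma_y reduces to the isotropic amplitude
  pa <- dog_params("anisotropic-5", sigma1x = 1, sigma1y = 1,
                   sigma2x = 2, sigma2y = 2, alpha = 0.3)
  expect_equal(normalizing_amplitude(pa), w, tolerance = 1e-12,
               ignore_attr = TRUE)
  bad <- p
  bad["sigma1"] <- -1
  expect_error(normalizing_amplitude(bad), "positive")
})

test_that("every rendered DoG equals the difference of two rendered Gaussians", {
  half <- 7
  sup <- kernel_support(15)
  # explicit amplitudes
  p4 <- dog_params("isotropic-4", w1 = 0.4, w2 = 0.15, sigma1 = 0.8,
                   sigma2 = 1.9)
  expect_equal(dog_kernel(p4, sup),
               oracle_gaussian_iso(0.4, 0.8, half) -
                 oracle_gaussian_iso(0.15, 1.9, half),
               tolerance = 1e-10)
  # normalized
  p2 <- dog_params("isotropic-2", sigma1 = 0.8, sigma2 = 1.6)
  w <- normalizing_amplitude(p2)
  expect_equal(dog_kernel(p2, sup),
               oracle_gaussian_iso(w[["w1"]], 0.8, half) -
                 oracle_gaussian_iso(w[["w2"]], 1.6, half),
               tolerance = 1e-10)
  # anisotropic, rotated
  p7 <- dog_params("anisotropic-7", w1 = 0.3, w2 = 0.1, sigma1x = 1.2,
                   sigma1y = 0.7, sigma2x = 2.4, sigma2y = 1.4,
                   alpha = 0.6)
  expect_equal(dog_kernel(p7, sup),
               oracle_gaussian_aniso(0.3, 1.2, 0.7, 0.6, half) -
                 oracle_gaussian_aniso(0.1, 2.4, 1.4, 0.6, half),
               tolerance = 1e-10)
})

test_that("normalized kernels are zero-DC band-pass filters", {
  sup <- kernel_support(31)  # >= 6 * max sigma per side
  expect_lt(abs(sum(dog_kernel(dog_params("isotropic-2", sigma1 = 0.8,
                                          sigma2 = 1.6), sup))), 1e-3)
  expect_lt(abs(sum(dog_kernel(dog_params("anisotropic-5", sigma1x = 1.1,
                                          sigma1y = 0.6, sigma2x = 2.0,
                                          sigma2y = 1.2, alpha = 1.1),
                               sup))), 1e-3)
})

test_that("degenerate and symmetric cases behave as the formulas dictate", {
  sup <- kernel_support(15)
  # equal Gaussians cancel exactly
  pz <- dog_params("isotropic-2", sigma1 = 1.3, sigma2 = 1.3)
  expect_true(all(dog_kernel(pz, sup) == 0))
  p4 <- dog_params("isotropic-4", w1 = 0.5, w2 = 0.5, sigma1 = 1.1,
                   sigma2 = 1.1)
  expect_true(all(dog_kernel(p4, sup) == 0))
  # origin value is w1 - w2 for explicit amplitudes
  p <- dog_params("isotropic-4", w1 = 0.7, w2 = 0.2, sigma1 = 0.9,
                  sigma2 = 2.2)
  expect_equal(dog_kernel(p, sup)[8, 8], 0.5, tolerance = 1e-12)
  # centro-symmetry k(x, y) = k(-x, -y)
  k <- dog_kernel(dog_params("anisotropic-7", w1 = .3, w2 = .1,
                             sigma1x = 1.5, sigma1y = 0.8, sigma2x = 2.5,
                             sigma2y = 1.6, alpha = 0.9), sup)
  expect_equal(k, k[15:1, 15:1], tolerance = 1e-14)
})

test_that("anisotropic kernels reduce to isotropic and are pi-periodic", {
  sup <- kernel_support(15)
  iso <- dog_kernel(dog_params("isotropic-2", sigma1 = 0.9, sigma2 = 1.8),
                    sup)
  for (a in c(0, 0.4, 2.2)) {
    an <- dog_kernel(dog_params("anisotropic-5", sigma1x = 0.9,
                                sigma1y = 0.9, sigma2x = 1.8,
                                sigma2y = 1.8, alpha = a), sup)
    expect_equal(an, iso, tolerance = 1e-12)
  }
  p <- function(a) dog_params("anisotropic-5", sigma1x = 2, sigma1y = 1,
                              sigma2x = 3, sigma2y = 1.5, alpha = a)
  expect_equal(dog_kernel(p(0.7), sup), dog_kernel(p(0.7 + pi), sup),
               tolerance = 1e-12)
})

test_that("rotating alpha rotates the kernel's sampling coordinates", {
  half <- 7
  p45 <- dog_params("anisotropic-7", w1 = 1, w2 = 0.3, sigma1x = 2,
                    sigma1y = 1, sigma2x = 3, sigma2y = 1.5,
                    alpha = pi / 4)
  expect_equal(dog_kernel(p45, kernel_support(15)),
               oracle_gaussian_aniso(1, 2, 1, pi / 4, half) -
                 oracle_gaussian_aniso(0.3, 3, 1.5, pi / 4, half),
               tolerance = 1e-10)
})

test_that("3D kernels modulate the 2D DoG along z", {
  sup <- kernel_support(15, 5)
  p3 <- dog_params("dog3d-6", w1 = 0.4, w2 = 0.15, sigma1 = 0.9,
                   sigma2 = 1.8, sigma1z = 1.5, sigma2z = 2.5)
  k3 <- dog_kernel(p3, sup)
  # central slice equals the 2D kernel with the same w, sigma
  k2 <- dog_kernel(dog_params("isotropic-4", w1 = 0.4, w2 = 0.15,
                              sigma1 = 0.9, sigma2 = 1.8),
                   kernel_support(15))
  expect_equal(k3[, , 3], k2, tolerance = 1e-14)
  # pointwise against direct evaluation at a few offsets
  for (off in list(c(2, -3, 1), c(0, 0, -2), c(-5, 4, 2))) {
    x <- off[1]; y <- off[2]; z <- off[3]
    expected <- 0.4 * exp(-(x^2 + y^2) / (2 * 0.9^2) - z^2 / (2 * 1.5^2)) -
      0.15 * exp(-(x^2 + y^2) / (2 * 1.8^2) - z^2 / (2 * 2.5^2))
    expect_equal(k3[y + 8, x + 8, z + 3], expected, tolerance = 1e-12)
  }
  # even function in all three coordinates
  expect_equal(k3, k3[15:1, 15:1, 5:1], tolerance = 1e-14)
  # shared z-bandwidth factors out: slice z / slice 0 is the constant
  # exp(-z^2 / (2 sigma_z^2)); distinct z-bandwidths break the constancy
  p_eq <- dog_params("dog3d-6", w1 = 0.4, w2 = 0.15, sigma1 = 0.9,
                     sigma2 = 1.8, sigma1z = 2, sigma2z = 2)
  ke <- dog_kernel(p_eq, sup)
  ratio <- ke[, , 4] / ke[, , 3]
  expect_equal(range(ratio), rep(exp(-1 / 8), 2), tolerance = 1e-9)
  ratio3 <- k3[, , 4] / k3[, , 3]  # sigma1z != sigma2z above
  expect_gt(diff(range(ratio3)), 1e-3)
})

test_that("analytic kernel gradients match central finite differences", {
  sup <- kernel_support(15, 5)
  cases <- list(
    dog_params("isotropic-2", sigma1 = 0.9, sigma2 = 1.7),
    dog_params("isotropic-4", w1 = .3, w2 = .2, sigma1 = 0.9, sigma2 = 1.7),
    dog_params("anisotropic-5", sigma1x = 0.9, sigma1y = 1.2,
               sigma2x = 1.7, sigma2y = 2.1, alpha = 0.7),
    dog_params("anisotropic-7", w1 = .3, w2 = .2, sigma1x = 0.9,
               sigma1y = 1.2, sigma2x = 1.7, sigma2y = 2.1, alpha = 0.7),
    dog_params("dog3d-6", w1 = .3, w2 = .2, sigma1 = 0.9, sigma2 = 1.7,
               sigma1z = 1.8, sigma2z = 3))
  for (p in cases) {
    gr <- dog_kernel_grad(p, sup)
    expect_named(gr, names(p))
    for (i in seq_along(p)) {
      h <- 1e-5
      pp <- p; pp[i] <- pp[i] + h
      pm <- p; pm[i] <- pm[i] - h
      fd <- (dog_kernel(pp, sup) - dog_kernel(pm, sup)) / (2 * h)
      expect_lt(max(abs(fd - gr[[i]])) / max(abs(gr[[i]])), 1e-4)
    }
  }
})

test_that("parameter validation rejects malformed filters", {
  expect_error(dog_params("isotropic-2", sigma1 = 0, sigma2 = 1),
               "positive")
  expect_error(dog_params("isotropic-2", sigma1 = 1), "requires")
  expect_error(kernel_support(14), "odd")
  # alpha reduced modulo pi
  p <- dog_params("anisotropic-5", sigma1x = 1, sigma1y = 2, sigma2x = 2,
                  sigma2y = 3, alpha = pi + 0.25)
  expect_equal(p[["alpha"]], 0.25, tolerance = 1e-12)
})
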