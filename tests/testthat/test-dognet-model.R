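test_that("parameter counting reproduces the printed architecture sizes", {
  # Shallow Isotropic: N=3, M=5, K=2, product head
  expect_identical(count_parameters(dognet_config(3, kind = "isotropic-2")),
                   62L)
  # Shallow Anisotropic
  expect_identical(count_parameters(dognet_config(3, kind = "anisotropic-5")),
                   107L)
  # minimal net
  expect_identical(count_parameters(
    dognet_config(1, filters_per_channel = 1, n_out = 1,
                  use_product = FALSE)), 4L)
  # other filter kinds count their parameters per filter
  expect_identical(count_parameters(dognet_config(3, kind = "isotropic-4")),
                   4L * 15L + 2L * 15L + 2L)
  expect_identical(count_parameters(dognet_config(2, kind = "dog3d-6",
                                                  filters_per_channel = 2)),
                   6L * 4L + 2L * 4L + 2L)
})

test_that("grid initialization spans [0.5, 2] and near-LoG priors", {
  expect_equal(init_sigma_grid(3), c(0.5, 1.25, 2.0))
  expect_equal(init_sigma_grid(5), c(0.5, 0.875, 1.25, 1.625, 2.0))
  expect_equal(init_sigma_grid(2), c(0.5, 2.0))
  expect_equal(init_sigma_grid(1), 1.25)
  params <- dognet_init(dognet_config(2, filters_per_channel = 3), seed = 4)
  for (n in 1:2) {
    s1 <- vapply(params[[1]]$beta[[n]], function(p) p[["sigma1"]], 0)
    s2 <- vapply(params[[1]]$beta[[n]], function(p) p[["sigma2"]], 0)
    expect_equal(s1, c(0.5, 1.25, 2.0))
    # difference-variance: sigma2^2 = sigma1^2 + 0.01
    expect_equal(s2^2 - s1^2, rep(0.01, 3), tolerance = 1e-12)
  }
  expect_equal(params[[1]]$zeta, c(0, 0))
  # same seed reproduces the parameter set exactly; different seed does not
  expect_identical(dognet_init(dognet_config(3), 9),
                   dognet_init(dognet_config(3), 9))
  expect_false(identical(dognet_init(dognet_config(3), 9)[[1]]$gamma,
                         dognet_init(dognet_config(3), 10)[[1]]$gamma))
})

test_that("the shallow forward pass is convolve, mix, bias, sigmoid", {
  cfg <- dognet_config(1, filters_per_channel = 1, n_out = 1,
                       use_product = FALSE, support_size = 7)
  params <- dognet_init(cfg, 1)
  params[[1]]$gamma[] <- 1
  params[[1]]$zeta <- 0
  # all-zero input -> sigmoid(0) = 0.5 everywhere
  z <- dognet_forward(array(0, c(9, 9, 1)), params, cfg)
  expect_true(all(z == 0.5))
  # impulse image: output = sigmoid of the kernel centered at the impulse
  x <- array(0, c(9, 9, 1)); x[5, 5, 1] <- 1
  out <- dognet_forward(x, params, cfg)
  k <- dog_kernel(params[[1]]$beta[[1]][[1]], cfg$support)
  expect_equal(out, 1 / (1 + exp(-oracle_conv2(x[, , 1], k))),
               tolerance = 1e-12)
  # shifting the bias shifts every pre-sigmoid value by the same constant
  params[[1]]$zeta <- 2
  out2 <- dognet_forward(x, params, cfg)
  pre <- function(m) log(m / (1 - m))
  expect_equal(pre(out2) - pre(out), matrix(2, 9, 9), tolerance = 1e-9)
})

test_that("pre-sigmoid shallow response is linear in the input", {
  cfg <- dognet_config(2, filters_per_channel = 2, n_out = 2,
                       support_size = 7)
  params <- dognet_init(cfg, 2)
  set.seed(11)
  x1 <- array(rnorm(81 * 2), c(9, 9, 2))
  x2 <- array(rnorm(81 * 2), c(9, 9, 2))
  pre_maps <- function(x) dognet_layer_forward(x, params[[1]],
                                               cfg$layers[[1]],
                                               cfg$support,
                                               cache = TRUE)$pre
  p1 <- pre_maps(x1); p2 <- pre_maps(x2); p12 <- pre_maps(2 * x1 - 3 * x2)
  zeta <- params[[1]]$zeta
  for (k in 1:2)
    expect_equal(p12[[k]] - zeta[k],
                 2 * (p1[[k]] - zeta[k]) - 3 * (p2[[k]] - zeta[k]),
                 tolerance = 1e-9)
})

test_that("the element-wise product acts as a soft AND", {
  a <- matrix(runif(25), 5); b <- matrix(runif(25), 5)
  p <- elementwise_product(list(a, b))
  expect_true(all(p <= pmin(a, b) + 1e-15))
  expect_equal(elementwise_product(list(a, matrix(1, 5, 5))), a)
  expect_equal(elementwise_product(list(matrix(0.9, 2, 2),
                                        matrix(0.8, 2, 2))),
               matrix(0.72, 2, 2))
  expect_error(elementwise_product(list(a)), "two maps")
  expect_error(elementwise_product(list(a, matrix(1, 4, 4))), "differ")
})

test_that("deep stacking composes layers and degenerates to shallow at T=1", {
  cfg1 <- dognet_config(2, filters_per_channel = 2, n_out = 2,
                        support_size = 7)
  cfg3 <- dognet_config(2, filters_per_channel = 2, n_out = 2, depth = 3,
                        support_size = 7)
  p1 <- dognet_init(cfg1, 5)
  p3 <- dognet_init(cfg3, 5)
  set.seed(21)
  x <- array(rnorm(81 * 2), c(9, 9, 2))
  out1 <- dognet_forward(x, p1, cfg1)
  maps <- dognet_layer_forward(x, p1[[1]], cfg1$layers[[1]], cfg1$support)
  expect_equal(out1, maps$maps[[1]] * maps$maps[[2]], tolerance = 1e-14)
  # T = 3: nested explicit composition oracle
  cur <- x
  for (t in 1:3) {
    lc <- cfg3$layers[[t]]
    maps <- lapply(1:2, function(k) {
      s <- matrix(p3[[t]]$zeta[k], 9, 9)
      for (n in seq_len(lc$n_in)) for (m in 1:2) {
        kern <- dog_kernel(p3[[t]]$beta[[n]][[m]], cfg3$support)
        s <- s + p3[[t]]$gamma[k, m, n] * oracle_conv2(cur[, , n], kern)
      }
      1 / (1 + exp(-s))
    })
    cur <- array(unlist(maps), c(9, 9, 2))
  }
  out3 <- dognet_forward(x, p3, cfg3)
  expect_equal(out3, cur[, , 1] * cur[, , 2], tolerance = 1e-10)
  expect_true(all(out3 > 0 & out3 < 1))
  # chain mismatch is rejected
  expect_error(dognet_config(layers = list(
    dognet_layer_config(2, 2, 3), dognet_layer_config(2, 2, 2)),
    n_channels = 2), "chan|outputs")
})

test_that("model gradients pass finite-difference checks on a 9x9 input", {
  set.seed(33)
  for (depth in c(1, 3)) {
    cfg <- dognet_config(2, filters_per_channel = 2, n_out = 2,
                         depth = depth, support_size = 7)
    params <- dognet_init(cfg, 3)
    x <- array(rnorm(81 * 2), c(9, 9, 2))
    y <- matrix(rbinom(81, 1, 0.2), 9, 9)
    bk <- dognet:::dognet_backward(x, y, params, cfg)
    ga <- dognet:::.flatten_grads(bk$grad)
    flat <- flatten_params(params)
    f <- function(v) softdice_loss(
      dognet_forward(x, unflatten_params(v, cfg), cfg), y)
    fd <- fd_grad(f, flat)
    rel <- abs(fd - ga[names(flat)]) /
      pmax(abs(fd), abs(ga[names(flat)]), 1e-8)
    expect_lt(max(rel), 1e-3)
  }
})

test_that("checkpoints round-trip config and parameters exactly", {
  cfg <- dognet_config(3, kind = "anisotropic-5")
  params <- dognet_init(cfg, 8)
  f <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(params, cfg, f)
  back <- read_checkpoint(f)
  expect_equal(flatten_params(back$params), flatten_params(params),
               tolerance = 1e-12)
  expect_identical(count_parameters(back$config), count_parameters(cfg))
  expect_identical(back$config$use_product, TRUE)
  # flatten/unflatten is the identity
  expect_equal(flatten_params(unflatten_params(flatten_params(params), cfg)),
               flatten_params(params))
})

test_that("forward pass validates channel counts and 3D kinds", {
  cfg <- dognet_config(3)
  params <- dognet_init(cfg, 1)
  expect_error(dognet_forward(array(0, c(9, 9, 2)), params, cfg),
               "channels")
  cfg3d <- dognet_config(1, kind = "dog3d-6", filters_per_channel = 1,
                         n_out = 1, use_product = FALSE)
  p3d <- dognet_init(cfg3d, 1)
  expect_error(dognet_forward(array(0, c(9, 9, 1)), p3d, cfg3d), "3D")
})
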