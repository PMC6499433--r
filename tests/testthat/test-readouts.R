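test_that("dense_drive matches a triple-loop oracle and handles edge cases", {
  set.seed(2)
  vals <- array(rnorm(4 * 3 * 3 * 2), c(4, 3, 3, 2))
  ft <- feature_tensor(vals)
  w <- array(rnorm(18), c(3, 3, 2))
  b <- 0.7
  oracle <- sapply(1:4, function(n) {
    s <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:2) {
      s <- s + vals[n, i, j, k] * w[i, j, k]
    }
    s + b
  })
  expect_equal(dense_drive(ft, w, b), oracle, tolerance = 1e-12)
  expect_equal(dense_drive(ft, array(0, c(3, 3, 2)), 2), rep(2, 4))
  onehot <- array(0, c(3, 3, 2))
  onehot[2, 3, 1] <- 1
  expect_equal(dense_drive(ft, onehot, b), vals[, 2, 3, 1] + b)
  expect_error(dense_drive(ft, rnorm(5)), "does not match")
})

test_that("factorized_drive equals dense_drive with the outer product", {
  set.seed(3)
  vals <- array(rnorm(5 * 4 * 4 * 3), c(5, 4, 4, 3))
  ft <- feature_tensor(vals)
  u <- matrix(rnorm(16), 4, 4)
  v <- rnorm(3)
  w <- array(as.vector(outer(as.vector(u), v)), c(4, 4, 3))
  expect_equal(factorized_drive(ft, u, v, 0.2), dense_drive(ft, w, 0.2),
               tolerance = 1e-12)
  # gauge freedom: (a u, v / a) leaves the drive unchanged
  expect_equal(factorized_drive(ft, 3 * u, v / 3, 0.2),
               factorized_drive(ft, u, v, 0.2), tolerance = 1e-12)
  u1 <- matrix(0, 4, 4)
  u1[2, 2] <- 1
  v1 <- c(0, 1, 0)
  expect_equal(factorized_drive(ft, u1, v1, 1), vals[, 2, 2, 2] + 1)
})

test_that("elu and shifted elu", {
  expect_identical(elu(0), 0)
  expect_equal(elu(c(1.5, 3)), c(1.5, 3))
  expect_equal(elu(-1), exp(-1) - 1)
  expect_equal(shifted_elu(1), 1)
  expect_equal(shifted_elu(2), 2)
  expect_equal(shifted_elu(0), exp(-1))
  expect_true(all(shifted_elu(seq(-20, 20, 0.5)) > 0))
})

test_that("tent basis: peaks, interpolation, partition of unity", {
  g <- tent_grid(50, -3, 6)
  expect_length(g$x, 50)
  tb <- tent_basis(g$x[7], g)
  expect_equal(tb[1, 7], 1)
  expect_equal(tb[1, -7], rep(0, 49))
  mid <- (g$x[3] + g$x[4]) / 2
  tbm <- tent_basis(mid, g)
  expect_equal(unname(tbm[1, 3:4]), c(0.5, 0.5))
  xs <- seq(-3, 6, length.out = 401)
  expect_equal(rowSums(tent_basis(xs, g)), rep(1, 401), tolerance = 1e-12)
})

test_that("output_nonlinearity composes h and g", {
  g <- tent_grid(50, -3, 6)
  x <- seq(-2.5, 5.5, length.out = 50)
  expect_equal(output_nonlinearity(x, rep(0, 50), g), shifted_elu(x))
  expect_equal(output_nonlinearity(x, rep(0.4, 50), g),
               exp(0.4) * shifted_elu(x), tolerance = 1e-12)
  j <- 11
  alpha <- rnorm(50)
  expect_equal(output_nonlinearity(g$x[j], alpha, g),
               exp(alpha[j]) * shifted_elu(g$x[j]))
  expect_true(all(output_nonlinearity(seq(-10, 10, 0.1), alpha, g) > 0))
})

test_that("lnp_rate is an exponential GLM in the pixels", {
  st <- noise_stack(3, side = 8, seed = 5, mean = 0, sd = 1)
  expect_equal(lnp_rate(st, matrix(0, 8, 8), 0.5), rep(exp(0.5), 3))
  w <- matrix(rnorm(64), 8, 8)
  r1 <- lnp_rate(st, w, 0)
  r2 <- lnp_rate(image_stack(2 * st$pixels, 70), w, 0)
  expect_equal(log(r2), 2 * log(r1), tolerance = 1e-10)
})

test_that("glm_rate applies the requested output nonlinearity", {
  fm <- matrix(rnorm(20), 4, 5)
  expect_equal(glm_rate(fm, rep(0, 5), 0, "exp"), rep(1, 4))
  expect_equal(glm_rate(fm, rep(0, 5), 0, "shifted_elu"), rep(exp(-1), 4))
  w <- rnorm(5)
  expect_true(all(glm_rate(fm, w, -3, "exp") > 0))
  expect_true(all(glm_rate(fm, w, -3, "shifted_elu") > 0))
})

test_that("parameter accounting reproduces the published table", {
  m <- init_cnn_model(cnn_core_spec(), n_neurons = 166, seed = 1)
  cp <- count_parameters(m)
  expect_identical(cp$core, 23936L)
  expect_identical(cp$readout_per_neuron, 867L)
  expect_identical(cp$total, 167858L)
  expect_identical(cp$total, 23936L + 166L * 867L)
  # introspective sum over stored tensors agrees
  core_len <- sum(sapply(m$conv, function(l) length(l$w) + length(l$b)))
  ro_len <- (length(m$u) + length(m$v) + length(m$b) + length(m$alpha)) /
    166L
  expect_identical(cp$core, as.integer(core_len))
  expect_identical(cp$readout_per_neuron, as.integer(ro_len))
  # LNP: one weight per pixel plus a bias
  lnp <- structure(list(W = matrix(0, 1600, 3), b = numeric(3), side = 40),
                   class = "lnp_model")
  expect_identical(count_parameters(lnp)$readout_per_neuron, 1601L)
  expect_identical(count_parameters(lnp, 166)$total, 265766L)
  # GFB: flattened bank dimensionality plus a bias
  gfb <- structure(list(W = matrix(0, 5544, 2), b = numeric(2)),
                   class = "gfb_glm_model")
  expect_identical(count_parameters(gfb)$readout_per_neuron, 5545L)
  expect_identical(count_parameters(gfb, 166)$total, 920470L)
  # pretrained GLM: 2 x 256 core, dense readout plus bias
  vgg <- structure(list(W = matrix(0, 25600, 2), b = numeric(2),
                        stats = list(mean = numeric(256),
                                     sd = rep(1, 256))),
                   class = "pretrained_glm_model")
  cpv <- count_parameters(vgg, 166)
  expect_identical(cpv$core, 512L)
  expect_identical(cpv$readout_per_neuron, 25601L)
  expect_identical(cpv$total, 4250278L)
})

test_that("cnn_forward geometry and degenerate single-layer reduction", {
  m <- init_cnn_model(cnn_core_spec(), n_neurons = 3, seed = 2)
  st <- noise_stack(2, side = 40, seed = 6, mean = 0, sd = 1, ppd = 35)
  x4 <- array(st$pixels, c(2, 40, 40, 1))
  fw <- v1sysid:::cnn_core_forward(m, x4, mode = "eval")
  expect_identical(dim(fw$features), c(2L, 28L, 28L, 32L))
  r <- cnn_forward(st, m)
  expect_identical(dim(r), c(2L, 3L))
  expect_true(all(is.finite(r) & r > 0))
  # 1x1 single-layer core with unit weight, fresh normalization statistics
  # and positive drive reduces to a factorized readout of the pixels
  m1 <- init_cnn_model(cnn_core_spec(n_layers = 1, channels = 1,
                                     first_kernel = 1),
                       n_neurons = 1, seed = 3)
  m1$conv[[1]]$w[] <- 1
  m1$conv[[1]]$b[] <- 10      # keeps every pre-activation positive
  m1$alpha[] <- 0
  sc <- sqrt(1 + 1e-5)
  expected <- shifted_elu(
    factorized_drive(array((st$pixels + 10) / sc, c(2, 40, 40, 1)),
                     matrix(m1$u[, 1], 40, 40), m1$v[, 1], m1$b[1]))
  expect_equal(as.vector(cnn_forward(st, m1)), expected, tolerance = 1e-10)
})
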