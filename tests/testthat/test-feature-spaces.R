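test_that("gabor_kernel size rule and symmetries", {
  # envelope scales of the published bank: sides 6, 11, 21 px
  sides <- sapply(c(1.5, 2.75, 5.25), function(s) {
    nrow(gabor_kernel(gabor_params(s, 1 / (4 * s)), 40))
  })
  expect_identical(sides, c(6L, 11L, 21L))
  # the image caps the kernel
  expect_identical(nrow(gabor_kernel(gabor_params(10, 0.02), 12)), 12L)
  # parity under point reflection: even for phi = 0, odd for phi = pi/2
  ke <- gabor_kernel(gabor_params(2, 0.12, 1, pi / 5, 0), 40)
  ko <- gabor_kernel(gabor_params(2, 0.12, 1, pi / 5, pi / 2), 40)
  flip <- function(m) m[nrow(m):1, ncol(m):1]
  expect_lt(max(abs(ke - flip(ke))), 1e-12)
  expect_lt(max(abs(ko + flip(ko))), 1e-12)
  # rotating theta by pi/2 rotates the kernel grid (gamma = 1, phi = 0)
  k0 <- gabor_kernel(gabor_params(2, 0.12, 1, pi / 7, 0), 40)
  k9 <- gabor_kernel(gabor_params(2, 0.12, 1, pi / 7 + pi / 2, 0), 40)
  expect_lt(max(abs(k9 - t(k0)[, nrow(k0):1])), 1e-10)
})

test_that("gfb_features equals a brute-force strided convolution oracle", {
  set.seed(1)
  toy <- image_stack(array(rnorm(2 * 12 * 12), c(2, 12, 12)), 70)
  cfg <- gfb_config(sizes_px = 5, n_freq = 2, n_orient = 3, stride = 2)
  ft <- gfb_features(toy, cfg)[[1]]
  k <- 5
  o <- floor(1 + (12 - k) / 2)
  pars <- v1sysid:::gfb_param_table(cfg, 1)
  worst <- 0
  for (q in seq_len(nrow(pars))) {
    for (ph in c(0, pi / 2)) {
      kern <- gabor_kernel(
        gabor_params(cfg$sigmas[1], pars$freq[q], pars$gamma[q],
                     pars$theta[q], ph), 12)
      ch <- 3 * q - 2 + (ph > 0)
      for (im in 1:2) for (a in 1:o) for (b in 1:o) {
        patch <- toy$pixels[im, (a - 1) * 2 + (1:k), (b - 1) * 2 + (1:k)]
        worst <- max(worst, abs(sum(patch * kern) -
                                  ft$values[im, a, b, ch]))
      }
    }
  }
  expect_lt(worst, 1e-8)
  # energy = even^2 + odd^2 channel-wise
  ev <- ft$values[, , , seq(1, dim(ft$values)[4], 3)]
  od <- ft$values[, , , seq(2, dim(ft$values)[4], 3)]
  en <- ft$values[, , , seq(3, dim(ft$values)[4], 3)]
  expect_equal(en, ev^2 + od^2, tolerance = 1e-12)
})

test_that("default bank geometry matches the published accounting", {
  st <- noise_stack(2, side = 40, seed = 2, ppd = 35)
  fs <- gfb_features(st)
  expect_identical(unname(sapply(fs, function(t) dim(t$values)[2])),
                   c(6L, 5L, 4L))
  expect_identical(gfb_feature_dim(), 5545L)
  expect_identical(ncol(flatten_features(fs)), 5544L)
  expect_identical(nrow(fs[[1]]$channel_labels), 72L)
})

test_that("energy channels are phase invariant and sign covariant", {
  cfg <- gfb_config()
  theta <- cfg$thetas[3]
  freq <- 2 / (4 * cfg$sigmas[2])
  gr <- grating_stack(theta, freq, seq(0, 2 * pi, length.out = 9)[-9],
                      side = 40)
  fs <- gfb_features(gr, cfg)
  lb <- fs[[2]]$channel_labels
  ch <- which(lb$type == "energy" & abs(lb$theta - theta) < 1e-9 &
                abs(lb$freq - freq) < 1e-9)
  en <- fs[[2]]$values[, , , ch]
  # center unit of the energy map across stimulus phase: < 1% variation
  ctr <- en[, 3, 3]
  expect_lt(diff(range(ctr)) / mean(ctr), 0.01)
  expect_true(all(fs[[2]]$values[, , , lb$type == "energy"] >= 0))
  # contrast inversion flips E and O, leaves A unchanged
  neg <- image_stack(-gr$pixels, gr$px_per_degree)
  fneg <- gfb_features(neg, cfg)
  for (s in 1:3) {
    lbs <- fs[[s]]$channel_labels
    eo <- lbs$type %in% c("even", "odd")
    expect_equal(fneg[[s]]$values[, , , eo], -fs[[s]]$values[, , , eo],
                 tolerance = 1e-10)
    expect_equal(fneg[[s]]$values[, , , !eo], fs[[s]]$values[, , , !eo],
                 tolerance = 1e-10)
  }
})

test_that("pretrained feature extraction geometry and degenerate nets", {
  st <- noise_stack(2, side = 40, seed = 3, ppd = 35)
  net <- init_convnet(vgg19_spec(), seed = 1)
  ft <- pretrained_features(st, net, "conv3_1")
  expect_identical(dim(ft$values), c(2L, 10L, 10L, 256L))
  expect_error(pretrained_features(st, net, "conv9_9"), "conv1_1")
  # an identity single-layer stand-in returns its input (pre-rectifier)
  id_spec <- convnet_spec(list(v1sysid:::conv_layer("ident", 1, kernel = 1)),
                          in_channels = 1)
  id_net <- init_convnet(id_spec, seed = 1)
  id_net$weights$ident$w[] <- 1
  id_net$weights$ident$b[] <- 0
  out <- pretrained_features(st, id_net, "ident")
  expect_equal(array(out$values, dim = c(2, 40, 40)), st$pixels,
               tolerance = 1e-12)
  # all-zero input through a zero-bias net gives all-zero features
  zero <- image_stack(array(0, c(1, 40, 40)), 35)
  net0 <- init_convnet(vgg19_spec(), seed = 2)
  for (nm in names(net0$weights)) net0$weights[[nm]]$b[] <- 0
  expect_true(all(pretrained_features(zero, net0, "conv2_1")$values == 0))
})

test_that("feature_norm standardizes channels and counts 2c parameters", {
  st <- noise_stack(6, side = 40, seed = 4, ppd = 35)
  net <- init_convnet(vgg19_spec(), seed = 5)
  raw <- pretrained_features(st, net, "conv3_1")
  nf <- feature_norm(raw)
  stats <- attr(nf, "feature_stats")
  z <- sweep(sweep(raw$values, 4, stats$mean, "-"), 4, stats$sd, "/")
  expect_lt(max(abs(apply(z, 4, mean))), 1e-6)
  expect_lt(max(abs(apply(z, 4, var) - 1)), 1e-3)
  expect_equal(nf$values, pmax(z, 0), tolerance = 1e-12)
  np <- attr(nf, "norm_params")
  expect_identical(length(np$scale) + length(np$offset), 512L)
  # constant channel: fallback path stays finite
  cst <- feature_tensor(array(3, c(4, 2, 2, 2)))
  expect_warning(out <- feature_norm(cst), "zero-variance")
  expect_true(all(is.finite(out$values)))
})

test_that("receptive fields compose recursively and grow with depth", {
  spec <- vgg19_spec()
  expect_identical(receptive_field_size(spec, "conv1_1")$px, 3)
  rf <- receptive_field_size(spec, "conv3_1", deg_per_px = (80 / 70) / 40)
  expect_identical(rf$px, 24)
  expect_equal(rf$degrees, 0.6857, tolerance = 1e-4)
  convs <- grep("^conv", vapply(spec$layers, `[[`, "", "name"),
                value = TRUE)
  sizes <- vapply(convs, function(nm) receptive_field_size(spec, nm)$px,
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})
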