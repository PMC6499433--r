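lag1_cor <- function(stack) {
  a <- stack$pixels[, , -dim(stack$pixels)[3]]
  b <- stack$pixels[, , -1]
  cor(as.vector(a), as.vector(b))
}

test_that("generate_stimuli: spectra, determinism, intensity scale", {
  white <- generate_stimuli(16, 80, spectral_exponent = 0, seed = 3)
  pink <- generate_stimuli(16, 80, spectral_exponent = 1, seed = 3)
  expect_lt(abs(lag1_cor(white)), 0.05)     # 16 * 80^2 > 1e5 samples
  expect_gt(lag1_cor(pink), lag1_cor(white))
  again <- generate_stimuli(16, 80, spectral_exponent = 0, seed = 3)
  expect_identical(white$pixels, again$pixels)
  expect_true(all(white$pixels >= 0 & white$pixels <= 255))
  # contrast matching was applied: disc mean is the background gray
  disc <- v1sysid:::match_region_mask(80, 70)
  expect_equal(mean(pink$pixels[1, , ][disc]), 128, tolerance = 1e-8)
})

test_that("ground_truth_rate implements rectified-linear and energy cells", {
  gp <- gabor_params(sigma = 3, freq = 1.5 / 12, theta = pi / 3, phi = 0)
  simple <- synthetic_neuron("simple", gp, gain = 2, baseline = 0.3)
  complexc <- synthetic_neuron("complex", gp, gain = 1, baseline = 0.2)
  # the zero stimulus is orthogonal to any filter: rate = baseline
  zero <- image_stack(array(0, c(1, 40, 40)), 35)
  expect_equal(ground_truth_rate(simple, zero), 0.3)
  expect_equal(ground_truth_rate(complexc, zero), 0.2)
  # anti-preferred stimulus is rectified away
  filt <- v1sysid:::neuron_filters(simple, 40)$even
  pref <- image_stack(array(filt, c(1, 40, 40)), 35)
  anti <- image_stack(array(-filt, c(1, 40, 40)), 35)
  expect_gt(ground_truth_rate(simple, pref), 0.3)
  expect_equal(ground_truth_rate(simple, anti), 0.3)
  # complex cell: rate invariant to the phase of a preferred grating
  gr <- grating_stack(pi / 3, 1.5 / 12, seq(0, 2 * pi, length.out = 17)[-17])
  r <- ground_truth_rate(complexc, gr)
  expect_lt(diff(range(r)) / mean(r), 0.01)
  # while the simple cell is strongly phase modulated
  rs <- ground_truth_rate(simple, gr)
  expect_gt(diff(range(rs)) / mean(rs), 0.5)
  # a filter that cannot be placed inside the image errors
  shifted <- synthetic_neuron("simple", gp, center = c(30, 0))
  expect_error(ground_truth_rate(shifted, image_stack(array(0, c(1, 40, 40)),
                                                      35)),
               "does not fit")
})

test_that("sample_responses is Poisson with the requested geometry", {
  expect_true(all(sample_responses(rep(0, 10), 3, seed = 1)$counts == 0))
  blk <- sample_responses(matrix(5, 2500, 1), n_reps = 40, seed = 2)
  draws <- as.vector(blk$counts)
  expect_lt(abs(mean(draws) - 5), 3 * sqrt(5 / length(draws)))
  # Fano factor ~ 1: variance across repeats approximates the mean
  set.seed(9)
  lam <- runif(300, 0.5, 4)
  blk2 <- sample_responses(matrix(lam, 300, 1), n_reps = 200, seed = 3)
  fano <- apply(blk2$counts[, , 1], 2, var) / lam
  expect_lt(abs(mean(fano) - 1), 0.05)
  expect_identical(sample_responses(lam, 4, seed = 7)$counts,
                   sample_responses(lam, 4, seed = 7)$counts)
  expect_error(sample_responses(c(-1, 2), 2, seed = 1), "nonnegative")
})

test_that("make_population respects composition, defaults and seeds", {
  expect_error(make_population(10, fraction_complex = 1.5), "\\[0, 1\\]")
  allsimple <- make_population(12, fraction_complex = 0, seed = 5)
  expect_true(all(sapply(allsimple, `[[`, "cell_type") == "simple"))
  expect_length(make_population(seed = 1), 166)
  p1 <- make_population(8, seed = 2)
  p2 <- make_population(8, seed = 2)
  expect_identical(p1, p2)
  thetas <- sapply(make_population(50, seed = 3),
                   function(s) s$gabor$theta)
  expect_true(all(thetas >= 0 & thetas < pi))
})

test_that("split_dataset produces disjoint exhaustive 64/16/20 splits", {
  sp <- split_dataset(100, seed = 4)
  expect_length(sp$test, 20)
  expect_length(sp$validation, 16)
  expect_length(sp$train, 64)
  all_idx <- c(sp$train, sp$validation, sp$test)
  expect_setequal(all_idx, 1:100)
  expect_length(all_idx, 100)
  expect_identical(sp, split_dataset(100, seed = 4))
  expect_false(identical(sp, split_dataset(100, seed = 5)))
})

test_that("explainable ratio of Poisson neurons matches the closed form", {
  # Var[rate] / (Var[rate] + E[rate]) is the infinite-repeat limit
  pop <- make_population(6, fraction_complex = 0.5, seed = 11)
  ds <- simulate_dataset(n_images = 1500, population = pop, n_reps = 8,
                         seed = 12)
  closed <- apply(ds$rates, 2, function(r) var(r) / (var(r) + mean(r)))
  est <- explainable_ratio(ds$responses)
  expect_equal(est, closed, tolerance = 0.06)
  # the default generator spans the 0.15 inclusion threshold
  pop_def <- make_population(60, seed = 13)
  ds2 <- simulate_dataset(n_images = 400, population = pop_def, n_reps = 4,
                          seed = 14)
  ratio <- explainable_ratio(ds2$responses)
  expect_gt(sum(ratio < 0.15), 0)
  expect_gt(sum(ratio >= 0.15), 10)
})
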