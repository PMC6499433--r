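test_that("poisson_loss values and input validation", {
  expect_equal(poisson_loss(rep(0, 4), rep(1, 4)), 4)
  expect_equal(poisson_loss(2, 2), 2 - 2 * log(2))
  expect_error(poisson_loss(1, 0), "positive")
  expect_error(poisson_loss(-1, 1), "nonnegative")
  # canonical-link stationarity: the exp-GLM gradient vanishes at r = y
  y <- c(1, 3, 0, 2)
  eps <- 1e-6
  at <- function(b) poisson_loss(y, exp(log(pmax(y, eps)) + b))
  expect_lt(abs((at(eps) - at(-eps)) / (2 * eps)), 1e-3)
})

test_that("adam reduces a fixed-batch training loss over early steps", {
  set.seed(12)
  X <- matrix(rnorm(200 * 20), 200, 20)
  wtrue <- rnorm(20, sd = 0.3)
  y <- matrix(rpois(200, exp(X %*% wtrue)), 200, 1)
  splits <- list(train = 1:160, validation = 161:200, test = integer(0))
  losses <- c()
  for (steps in c(5, 60)) {
    fit <- v1sysid:::fit_readout_glm(
      X, y, splits, output = "exp",
      reg = reg_config(lambda_sparse = 0, lambda_laplace = 0,
                       lambda_group = 0),
      cfg = train_config(batch_size = 160, eval_every = 5, patience = 3,
                         n_decays = 1, initial_lr = 0.05, max_steps = steps,
                         seed = 1))
    losses <- c(losses, fit$best_val)
  }
  expect_lt(losses[2], losses[1])
})

test_that("early stopping returns parameters at least as good as the start", {
  set.seed(13)
  X <- matrix(rnorm(300 * 15), 300, 15)
  y <- matrix(rpois(300, exp(0.4 * X[, 1])), 300, 1)
  splits <- list(train = 1:240, validation = 241:300, test = integer(0))
  cfg <- train_config(batch_size = 120, eval_every = 10, patience = 2,
                      n_decays = 1, initial_lr = 0.02, max_steps = 300,
                      seed = 2)
  fit <- v1sysid:::fit_readout_glm(X, y, splits, output = "exp",
                                   reg = reg_config(0, 0, 0), cfg = cfg)
  expect_equal(fit$best_val, min(fit$history$val_loss))
  expect_lte(fit$best_val, fit$history$val_loss[1])
  # identical seeds give identical fits
  fit2 <- v1sysid:::fit_readout_glm(X, y, splits, output = "exp",
                                    reg = reg_config(0, 0, 0), cfg = cfg)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$best_val, fit2$best_val)
})

test_that("all-zero features drive the intercept to log mean rate", {
  set.seed(14)
  y <- matrix(rpois(400, 2.3), 400, 1)
  X <- matrix(0, 400, 5)
  # validation = train isolates the closed-form optimum b* = log(mean y)
  splits <- list(train = 1:400, validation = 1:400, test = integer(0))
  fit <- v1sysid:::fit_readout_glm(
    X, y, splits, output = "exp", reg = reg_config(),
    cfg = train_config(batch_size = 400, eval_every = 10, patience = 3,
                       n_decays = 2, initial_lr = 0.01, max_steps = 200,
                       seed = 3))
  expect_lt(max(abs(fit$params$W)), 1e-6)
  expect_equal(unname(fit$params$b), log(mean(y)), tolerance = 1e-3)
})

test_that("training aborts with a diagnostic on non-finite loss", {
  params <- list(w = 0)
  bad_grad <- function(p, idx) list(grads = list(w = 0), loss = NaN)
  expect_error(
    v1sysid:::sgd_fit(params, bad_grad, function(p) 1, n_train = 10,
                      cfg = train_config(batch_size = 2, max_steps = 5,
                                         seed = 1)),
    "diverged")
})

test_that("grid_search machinery: combinatorics, selection, tie-breaking", {
  # stub fitter: validation loss is a deterministic function of the config,
  # different across three synthetic neurons
  fitter <- function(reg) {
    list(val_per_neuron = c(
      abs(log10(reg$lambda_sparse) + 2),          # prefers 1e-2
      abs(log10(reg$lambda_sparse) + 3),          # prefers 1e-3
      0))                                         # ties everywhere
  }
  gs <- grid_search(fitter, grids = list(lambda_sparse = 10^seq(-3, 0)))
  expect_identical(nrow(gs$configs), 4L)
  expect_length(gs$fits, 4)
  expect_equal(gs$configs$lambda_sparse[gs$best_config[1]], 1e-2)
  expect_equal(gs$configs$lambda_sparse[gs$best_config[2]], 1e-3)
  # ties break toward the strongest regularization
  expect_equal(gs$configs$lambda_sparse[gs$best_config[3]], 1)
  # a full 3-grid search enumerates 4^3 = 64 configurations
  gs3 <- grid_search(function(reg) list(val_per_neuron = 0),
                     grids = list(lambda_sparse = 10^seq(-3, 0),
                                  lambda_laplace = 10^seq(-3, 0),
                                  lambda_group = 10^seq(-3, 0)))
  expect_identical(nrow(gs3$configs), 64L)
  # single-point grid returns that config
  gs1 <- grid_search(function(reg) list(val_per_neuron = c(1, 2)),
                     grids = list(lambda_sparse = 0.05))
  expect_true(all(gs1$best_config == 1L))
  expect_error(grid_search(fitter, grids = list(0.1)), "named")
})

test_that("grid search on a real toy rejects over-penalization", {
  set.seed(16)
  n <- 500
  X <- matrix(rnorm(n * 30), n, 30)
  w <- numeric(30)
  w[c(3, 11, 25)] <- c(0.8, -0.6, 0.7)
  y <- matrix(rpois(n, exp(X %*% w)), n, 1)
  splits <- list(train = 1:320, validation = 321:400, test = 401:500)
  fitter <- function(reg) {
    v1sysid:::fit_readout_glm(
      X, y, splits, output = "exp", reg = reg,
      cfg = train_config(batch_size = 160, eval_every = 20, patience = 3,
                         n_decays = 1, initial_lr = 0.02, max_steps = 400,
                         seed = 4))
  }
  gs <- grid_search(fitter, grids = list(lambda_sparse = c(0.001, 0.01,
                                                           0.1, 10)),
                    base = reg_config(lambda_laplace = 0, lambda_group = 0))
  picked <- gs$configs$lambda_sparse[gs$best_config[1]]
  expect_true(picked > 0)      # some sparsity is selected
  expect_lt(picked, 10)        # the over-penalized grid point is rejected
})

test_that("pretrained-feature GLM fits with training-split normalization", {
  set.seed(17)
  small <- convnet_spec(list(
    v1sysid:::conv_layer("conv1_1", 4),
    v1sysid:::pool_layer("pool1"),
    v1sysid:::conv_layer("conv2_1", 6)), in_channels = 1)
  net <- init_convnet(small, seed = 18)
  stim <- noise_stack(400, side = 16, seed = 19, mean = 0, sd = 1, ppd = 35)
  # a ground-truth neuron driven by one unit of one feature channel
  raw <- pretrained_features(stim, net, "conv2_1")
  drive <- 0.8 * scale(raw$values[, 4, 4, 3])
  y <- matrix(rpois(400, exp(drive)), 400, 1)
  splits <- split_dataset(400, seed = 20)
  fit <- fit_pretrained_glm(stim, y, splits, net, "conv2_1",
                            cfg = train_config(batch_size = 128,
                                               eval_every = 20, patience = 4,
                                               n_decays = 2,
                                               initial_lr = 2e-3,
                                               max_steps = 1200, seed = 21))
  expect_s3_class(fit, "pretrained_glm_model")
  # stored statistics come from the training split only
  expect_equal(fit$stats$mean,
               apply(raw$values[splits$train, , , , drop = FALSE], 4, mean))
  r <- predict_rate(fit, stim)
  expect_true(all(is.finite(r) & r > 0))
  # the fit beats the intercept-only model on held-out data
  rt <- r[splits$test, 1]
  yt <- y[splits$test, 1]
  base <- mean(y[splits$train, ])
  expect_lt(poisson_loss(yt, rt), poisson_loss(yt, rep(base, length(yt))))
  # the readout energy profile concentrates on few of the 6 channels
  prof <- readout_energy_profile(fit$W[, 1], shape = fit$shape)
  expect_identical(nrow(prof), 6L)
  expect_gt(prof$cumulative[2], 0.4)
})
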