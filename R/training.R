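#' Training configuration
#'
#' Mini-batch Poisson fitting with early stopping: validation loss is
#' evaluated every `eval_every` steps; after `patience` evaluations without
#' improvement the best parameters are restored and the learning rate is
#' divided by `lr_decay`; training stops after `n_decays` decays (or at
#' `max_steps`).
#'
#' @param batch_size mini-batch size (default 256).
#' @param eval_every steps between validation evaluations (default 100).
#' @param patience evaluations without improvement before a decay
#'   (default 10).
#' @param lr_decay learning-rate decay factor (default 3).
#' @param n_decays decays before stopping (default 3).
#' @param initial_lr Adam learning rate at the start (default 1e-4).
#' @param max_steps hard cap on optimization steps (default `Inf`; set a
#'   finite value for desk-scale runs).
#' @param seed governs parameter initialization and batch shuffling.
#' @param verbose emit a structured log line per evaluation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 256L, eval_every = 100L,
                         patience = 10L, lr_decay = 3, n_decays = 3L,
                         initial_lr = 1e-4, max_steps = Inf, seed = 1L,
                         verbose = FALSE) {
  stopifnot(batch_size >= 1, eval_every >= 1, patience >= 1, lr_decay > 1,
            n_decays >= 0, initial_lr > 0, max_steps > 0)
  structure(list(batch_size = as.integer(batch_size),
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience), lr_decay = lr_decay,
                 n_decays = as.integer(n_decays), initial_lr = initial_lr,
                 max_steps = max_steps, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Poisson negative log-likelihood (up to the `log y!` constant)
#'
#' `sum(r - y * log(r))` over all samples (and neurons, when matrices are
#' given).
#'
#' @param y observed counts (`>= 0`).
#' @param r predicted rates (`> 0`), same shape.
#' @return scalar loss.
#' @export
poisson_loss <- function(y, r) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("rates must be finite and strictly positive")
  }
  if (any(y < 0)) stop("counts must be nonnegative")
  sum(r - y * log(r))
}

# exp with a clamped argument and a positive floor: a numerical guard against
# transient overflow/underflow during stochastic optimization (never binding
# at convergence)
safe_exp <- function(x) pmax(exp(pmin(x, 60)), 1e-12)

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) {p[] <- 0; p})
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- Generic mini-batch loop with early stopping ---------------------------

# params: named list of arrays. grad_fn(params, idx) -> list(grads, loss).
# val_fn(params) -> scalar validation loss. Returns the best-validation
# parameters, the validation history and the best step.
sgd_fit <- function(params, grad_fn, val_fn, n_train, cfg) {
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old))
  state <- adam_init(params)
  lr <- cfg$initial_lr
  best_val <- val_fn(params)
  best_params <- params
  best_step <- 0L
  since_best <- 0L
  decays <- 0L
  history <- data.frame(step = 0L, val_loss = best_val, lr = lr)
  step <- 0L
  order_idx <- sample.int(n_train)
  pos <- 1L
  while (step < cfg$max_steps) {
    step <- step + 1L
    if (pos + cfg$batch_size - 1L > n_train) {
      order_idx <- sample.int(n_train)
      pos <- 1L
    }
    take <- min(cfg$batch_size, n_train)
    idx <- order_idx[pos:(pos + take - 1L)]
    pos <- pos + take
    gl <- grad_fn(params, idx)
    if (!is.finite(gl$loss)) {
      stop(sprintf("training diverged at step %d (non-finite loss)", step))
    }
    upd <- adam_step(params, gl$grads, state, lr)
    params <- upd$params
    state <- upd$state
    if (step %% cfg$eval_every == 0L) {
      vl <- val_fn(params)
      history <- rbind(history,
                       data.frame(step = step, val_loss = vl, lr = lr))
      if (cfg$verbose) {
        message(sprintf("step=%d train_loss=%.5g val_loss=%.5g lr=%.3g",
                        step, gl$loss, vl, lr))
      }
      if (vl < best_val) {
        best_val <- vl
        best_params <- params
        best_step <- step
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (since_best >= cfg$patience) {
        params <- best_params
        if (decays >= cfg$n_decays) break
        decays <- decays + 1L
        lr <- lr / cfg$lr_decay
        state <- adam_init(params)
        since_best <- 0L
      }
    }
  }
  list(params = best_params, history = history, best_step = best_step,
       best_val = best_val)
}

# mask-aware mean spike count per (image, neuron)
mean_counts <- function(block) {
  stopifnot(inherits(block, "response_block"))
  cnt <- block$counts
  cnt[!block$mask] <- 0
  nv <- apply(block$mask, c(2, 3), sum)
  if (any(nv == 0)) stop("some (image, neuron) pairs have no valid repeat")
  apply(cnt, c(2, 3), sum) / nv
}

# ---- Readout GLM family (LNP / GFB / pretrained features) ------------------

# X: n x D design matrix; Y: n x n_neurons mean counts. shape = c(h, w, c)
# enables the spatial penalties; NULL restricts to L1. output: link inverse.
fit_readout_glm <- function(X, Y, splits, shape = NULL,
                            output = c("exp", "shifted_elu"),
                            reg = reg_config(), cfg = train_config()) {
  output <- match.arg(output)
  stopifnot(nrow(X) == nrow(Y))
  D <- ncol(X)
  nn <- ncol(Y)
  Xtr <- X[splits$train, , drop = FALSE]
  Ytr <- Y[splits$train, , drop = FALSE]
  Xva <- X[splits$validation, , drop = FALSE]
  Yva <- Y[splits$validation, , drop = FALSE]
  rate_fn <- if (output == "exp") safe_exp else shifted_elu
  drate_fn <- if (output == "exp") safe_exp else shifted_elu_deriv
  # intercept init: match the mean training rate under the link
  mu <- pmax(colMeans(Ytr), 1e-3)
  b0 <- if (output == "exp") log(mu) else ifelse(mu >= 1, mu, log(mu) + 1)
  params <- list(W = matrix(0, D, nn), b = b0)
  penal_grad <- function(W) {
    G <- l1_grad(W, reg$lambda_sparse)
    if (!is.null(shape) && (reg$lambda_laplace > 0 || reg$lambda_group > 0)) {
      for (j in seq_len(nn)) {
        wj <- array(W[, j], dim = shape)
        gj <- 0
        if (reg$lambda_laplace > 0) {
          gj <- gj + laplacian_grad(wj, reg$lambda_laplace)
        }
        if (reg$lambda_group > 0) gj <- gj + group_grad(wj, reg$lambda_group)
        G[, j] <- G[, j] + as.vector(gj)
      }
    }
    G
  }
  # mini-batch objective: mean Poisson loss per sample plus the penalties
  # (the scale convention the published penalty optima were tuned under)
  grad_fn <- function(p, idx) {
    Xb <- Xtr[idx, , drop = FALSE]
    Yb <- Ytr[idx, , drop = FALSE]
    drive <- sweep(Xb %*% p$W, 2, p$b, "+")
    r <- rate_fn(drive)
    dd <- if (output == "exp") {
      r - Yb
    } else {
      (1 - Yb / r) * drate_fn(drive)
    }
    dd <- dd / nrow(Xb)
    list(grads = list(W = crossprod(Xb, dd) + penal_grad(p$W),
                      b = colSums(dd)),
         loss = poisson_loss(Yb, r) / nrow(Xb))
  }
  val_per_neuron <- function(p) {
    r <- rate_fn(sweep(Xva %*% p$W, 2, p$b, "+"))
    colSums(r - Yva * log(r)) / nrow(Yva)
  }
  fit <- sgd_fit(params, grad_fn, function(p) sum(val_per_neuron(p)),
                 nrow(Xtr), cfg)
  fit$val_per_neuron <- val_per_neuron(fit$params)
  fit$output <- output
  fit
}

#' Fit the regularized LNP model
#'
#' One exponential-nonlinearity pixel filter per neuron
#' (`rate = exp(w . x + b)`), Poisson loss, with sparsity and Laplacian
#' smoothness penalties on the filter.
#'
#' @param stimuli z-scored [image_stack()] of model inputs.
#' @param responses a [response_block()] (or `n_images x n_neurons` matrix of
#'   mean counts).
#' @param splits a [split_dataset()] result.
#' @param reg a [reg_config()]; group sparsity is not applicable to the
#'   single-channel pixel filter and defaults to 0.
#' @param cfg a [train_config()].
#' @return An object of class `lnp_model` (fields `W` = `D x n_neurons`
#'   filters, `b`, `side`, and the `fit` record).
#' @export
fit_lnp <- function(stimuli, responses, splits,
                    reg = reg_config(lambda_group = 0),
                    cfg = train_config()) {
  stopifnot(inherits(stimuli, "image_stack"))
  Y <- if (inherits(responses, "response_block")) mean_counts(responses)
       else as.matrix(responses)
  side <- side_px(stimuli)
  X <- matrix(stimuli$pixels, nrow = n_images(stimuli))
  fit <- fit_readout_glm(X, Y, splits, shape = c(side, side, 1L),
                         output = "exp", reg = reg, cfg = cfg)
  structure(list(W = fit$params$W, b = fit$params$b, side = side,
                 reg = reg, fit = fit["history"],
                 val_per_neuron = fit$val_per_neuron),
            class = "lnp_model")
}

#' @export
predict_rate.lnp_model <- function(model, images, ...) {
  X <- matrix(images$pixels, nrow = n_images(images))
  safe_exp(sweep(X %*% model$W, 2, model$b, "+"))
}

#' @export
count_parameters.lnp_model <- function(model, n_neurons = NULL) {
  if (is.null(n_neurons)) n_neurons <- ncol(model$W)
  readout <- nrow(model$W) + 1L
  list(core = 0L, readout_per_neuron = as.integer(readout),
       total = as.integer(n_neurons * readout))
}

#' Fit the Gabor filter bank GLM
#'
#' Dense readout over the even/odd/energy feature maps of the quadrature
#' Gabor filter bank, a shifted-ELU output nonlinearity, Poisson loss, and an
#' L1 penalty on the readout weights (the bank's readout uses sparsity only).
#'
#' @inheritParams fit_lnp
#' @param gfb a [gfb_config()].
#' @param reg a [reg_config()]; defaults to the bank's published L1 strength
#'   0.05 with the spatial penalties off.
#' @return An object of class `gfb_glm_model`.
#' @details The flattened bank features are standardized (per feature, using
#'   training-split statistics) before the readout. The raw even/odd and
#'   energy features differ in scale by orders of magnitude, which would both
#'   destabilize first-order optimization and let the single L1 penalty act
#'   with very different strengths across channels — the same argument the
#'   source model comparison makes for normalizing its pretrained features.
#'   The statistics are stored in the model and reapplied at prediction time.
#' @export
fit_gfb_glm <- function(stimuli, responses, splits, gfb = gfb_config(),
                        reg = reg_config(lambda_sparse = 0.05,
                                         lambda_laplace = 0,
                                         lambda_group = 0),
                        cfg = train_config()) {
  stopifnot(inherits(stimuli, "image_stack"))
  Y <- if (inherits(responses, "response_block")) mean_counts(responses)
       else as.matrix(responses)
  X <- flatten_features(gfb_features(stimuli, gfb))
  fm <- colMeans(X[splits$train, , drop = FALSE])
  fs <- apply(X[splits$train, , drop = FALSE], 2, sd)
  fs[!is.finite(fs) | fs < 1e-12] <- 1
  X <- sweep(sweep(X, 2, fm, "-"), 2, fs, "/")
  fit <- fit_readout_glm(X, Y, splits, shape = NULL, output = "shifted_elu",
                         reg = reg, cfg = cfg)
  structure(list(W = fit$params$W, b = fit$params$b, gfb = gfb, reg = reg,
                 feat_mean = fm, feat_sd = fs, fit = fit["history"],
                 val_per_neuron = fit$val_per_neuron),
            class = "gfb_glm_model")
}

#' @export
predict_rate.gfb_glm_model <- function(model, images, ...) {
  X <- flatten_features(gfb_features(images, model$gfb))
  X <- sweep(sweep(X, 2, model$feat_mean, "-"), 2, model$feat_sd, "/")
  shifted_elu(sweep(X %*% model$W, 2, model$b, "+"))
}

#' @export
count_parameters.gfb_glm_model <- function(model, n_neurons = NULL) {
  if (is.null(n_neurons)) n_neurons <- ncol(model$W)
  readout <- nrow(model$W) + 1L
  list(core = 0L, readout_per_neuron = as.integer(readout),
       total = as.integer(n_neurons * readout))
}

#' Fit the pretrained-feature GLM
#'
#' Dense readout with an exponential output nonlinearity over the
#' standardized, rectified feature maps of one layer of a fixed convolutional
#' network; Poisson loss with sparsity, Laplacian smoothness and group
#' sparsity penalties. Feature-normalization statistics are computed on the
#' training split only.
#'
#' @inheritParams fit_lnp
#' @param net a `convnet` from [init_convnet()].
#' @param layer_name which layer's features to read out (default
#'   `"conv3_1"`).
#' @return An object of class `pretrained_glm_model`.
#' @export
fit_pretrained_glm <- function(stimuli, responses, splits, net,
                               layer_name = "conv3_1", reg = reg_config(),
                               cfg = train_config()) {
  stopifnot(inherits(stimuli, "image_stack"))
  Y <- if (inherits(responses, "response_block")) mean_counts(responses)
       else as.matrix(responses)
  raw <- pretrained_features(stimuli, net, layer_name)
  tr_stats <- list(
    mean = apply(raw$values[splits$train, , , , drop = FALSE], 4, mean),
    sd = apply(raw$values[splits$train, , , , drop = FALSE], 4, sd))
  feats <- feature_norm(raw, stats = tr_stats)
  shape <- dim(feats$values)[2:4]
  X <- flatten_features(feats)
  fit <- fit_readout_glm(X, Y, splits, shape = shape, output = "exp",
                         reg = reg, cfg = cfg)
  structure(list(W = fit$params$W, b = fit$params$b, net = net,
                 layer_name = layer_name, stats = tr_stats, shape = shape,
                 reg = reg, fit = fit["history"],
                 val_per_neuron = fit$val_per_neuron),
            class = "pretrained_glm_model")
}

#' @export
predict_rate.pretrained_glm_model <- function(model, images, ...) {
  raw <- pretrained_features(images, model$net, model$layer_name)
  X <- flatten_features(feature_norm(raw, stats = model$stats))
  safe_exp(sweep(X %*% model$W, 2, model$b, "+"))
}

#' @export
count_parameters.pretrained_glm_model <- function(model, n_neurons = NULL) {
  if (is.null(n_neurons)) n_neurons <- ncol(model$W)
  core <- 2L * length(model$stats$mean)   # per-channel scale and offset
  readout <- nrow(model$W) + 1L
  list(core = as.integer(core), readout_per_neuron = as.integer(readout),
       total = as.integer(core + n_neurons * readout))
}

# ---- Data-driven CNN -------------------------------------------------------

# full forward/backward for one mini-batch; returns grads as a flat named
# list matching cnn_params()/cnn_set_params()
cnn_batch_grad <- function(model, x4, Yb, reg) {
  spec <- model$core
  nl <- spec$n_layers
  B <- dim(x4)[1]
  fw <- cnn_core_forward(model, x4, mode = "train")
  feats <- fw$features
  dfe <- dim(feats)
  fm <- matrix(feats, nrow = B)
  nn <- ncol(model$u)
  P <- nrow(model$u)
  C <- nrow(model$v)
  W <- matrix(0, P * C, nn)
  for (j in seq_len(nn)) W[, j] <- as.vector(outer(model$u[, j], model$v[, j]))
  drive <- sweep(fm %*% W, 2, model$b, "+")
  hexp <- matrix(0, B, nn)
  for (j in seq_len(nn)) {
    hexp[, j] <- exp(tent_basis(drive[, j], model$grid) %*% model$alpha[, j])
  }
  g <- shifted_elu(drive)
  r <- hexp * g
  loss <- poisson_loss(Yb, r) / B
  dLdr <- (1 - Yb / r) / B    # batch-mean loss convention
  # alpha gradient: dr/dalpha_i = r * t_i(drive)
  galpha <- matrix(0, nrow(model$alpha), nn)
  dDrive <- matrix(0, B, nn)
  for (j in seq_len(nn)) {
    Tj <- tent_basis(drive[, j], model$grid)
    Tdj <- tent_basis_deriv(drive[, j], model$grid)
    galpha[, j] <- crossprod(Tj, dLdr[, j] * r[, j]) +
      output_nl_grad(model$alpha[, j], reg$lambda_out)
    dhdx <- hexp[, j] * as.vector(Tdj %*% model$alpha[, j])
    dDrive[, j] <- dLdr[, j] *
      (dhdx * g[, j] + hexp[, j] * shifted_elu_deriv(drive[, j]))
  }
  gb <- colSums(dDrive)
  gW <- crossprod(fm, dDrive)                  # (P*C) x nn
  gu <- matrix(0, P, nn)
  gv <- matrix(0, C, nn)
  for (j in seq_len(nn)) {
    wj <- matrix(gW[, j], P, C)
    gu[, j] <- wj %*% model$v[, j]
    gv[, j] <- crossprod(wj, model$u[, j])
  }
  gu <- gu + l1_grad(model$u, reg$lambda_sparse)
  gv <- gv + l1_grad(model$v, reg$lambda_sparse)
  dfm <- dDrive %*% t(W)
  # gradient wrt the last layer's BN output, as an (N*h*w) x C matrix view
  dx <- matrix(array(dfm, dim = dfe), prod(dfe[1:3]), dfe[4])
  # back through the core
  gconv <- vector("list", nl)
  core_pen <- core_filter_grads(model$conv, reg)
  for (l in rev(seq_len(nl))) {
    cc <- fw$cache[[l]]
    nr <- nrow(cc$act)
    s <- sqrt(cc$var + 1e-5)
    xhat <- (cc$act - rep(cc$mean, each = nr)) / rep(s, each = nr)
    # batch-norm backward (no affine), batch statistics
    dact <- (dx - rep(colMeans(dx), each = nr) -
               xhat * rep(colMeans(dx * xhat), each = nr)) /
      rep(s, each = nr)
    dpre <- dact * elu_deriv(cc$pre)
    k <- if (l == 1L) spec$first_kernel else spec$later_kernel
    pad <- if (l == 1L) 0L else (k - 1L) %/% 2L
    dxin <- cc$in_dim
    wmat <- matrix(model$conv[[l]]$w, k * k * dxin[4],
                   dim(model$conv[[l]]$w)[4])
    gw <- array(crossprod(cc$cols, dpre), dim = dim(model$conv[[l]]$w)) +
      core_pen[[l]]
    gconv[[l]] <- list(w = gw, b = colSums(dpre))
    if (l > 1L) {
      dxa <- col2im_nhwc(dpre %*% t(wmat), dxin[1], dxin[2], dxin[3],
                         dxin[4], k, k, 1L, pad)
      dx <- matrix(dxa, prod(dxin[1:3]), dxin[4])
    }
  }
  grads <- list(u = gu, v = gv, b = gb, alpha = galpha)
  for (l in seq_len(nl)) {
    grads[[paste0("conv_w", l)]] <- gconv[[l]]$w
    grads[[paste0("conv_b", l)]] <- gconv[[l]]$b
  }
  list(grads = grads, loss = loss, bn = fw$bn)
}

cnn_params <- function(model) {
  p <- list(u = model$u, v = model$v, b = model$b, alpha = model$alpha)
  for (l in seq_along(model$conv)) {
    p[[paste0("conv_w", l)]] <- model$conv[[l]]$w
    p[[paste0("conv_b", l)]] <- model$conv[[l]]$b
  }
  p
}

cnn_set_params <- function(model, p) {
  model$u <- p$u
  model$v <- p$v
  model$b <- p$b
  model$alpha <- p$alpha
  for (l in seq_along(model$conv)) {
    model$conv[[l]]$w <- p[[paste0("conv_w", l)]]
    model$conv[[l]]$b <- p[[paste0("conv_b", l)]]
  }
  model
}

#' Fit the data-driven CNN model
#'
#' Trains the convolutional core, the per-neuron factorized readouts, and the
#' per-neuron learned output nonlinearities jointly by mini-batch Adam on the
#' Poisson loss, with Laplacian smoothness on the first-layer filters, group
#' sparsity on later filters, L1 on the readout factors, and the finite-
#' difference penalty on the output-nonlinearity coefficients. Early stopping
#' as in [train_config()].
#'
#' @inheritParams fit_lnp
#' @param core a [cnn_core_spec()].
#' @param reg a [reg_config()].
#' @param grid a [tent_grid()] for the output nonlinearities.
#' @return A fitted `cnn_model`.
#' @export
fit_cnn <- function(stimuli, responses, splits, core = cnn_core_spec(),
                    reg = reg_config(), cfg = train_config(),
                    grid = tent_grid()) {
  stopifnot(inherits(stimuli, "image_stack"))
  Y <- if (inherits(responses, "response_block")) mean_counts(responses)
       else as.matrix(responses)
  side <- side_px(stimuli)
  model <- init_cnn_model(core, n_neurons = ncol(Y), input_side = side,
                          grid = grid, seed = cfg$seed)
  n <- n_images(stimuli)
  x_all <- array(stimuli$pixels, dim = c(n, side, side, 1L))
  xtr <- x_all[splits$train, , , , drop = FALSE]
  Ytr <- Y[splits$train, , drop = FALSE]
  val_stim <- image_stack(
    stimuli$pixels[splits$validation, , , drop = FALSE],
    stimuli$px_per_degree)
  Yva <- Y[splits$validation, , drop = FALSE]
  # model state (bn running stats) updated by closure side effects
  env <- new.env()
  env$model <- model
  grad_fn <- function(p, idx) {
    env$model <- cnn_set_params(env$model, p)
    out <- cnn_batch_grad(env$model, xtr[idx, , , , drop = FALSE],
                          Ytr[idx, , drop = FALSE], reg)
    env$model$bn <- out$bn
    list(grads = out$grads, loss = out$loss)
  }
  val_fn <- function(p) {
    env$model <- cnn_set_params(env$model, p)
    r <- cnn_forward(val_stim, env$model)
    poisson_loss(Yva, r) / nrow(Yva)
  }
  fit <- sgd_fit(cnn_params(model), grad_fn, val_fn, nrow(Ytr), cfg)
  model <- cnn_set_params(env$model, fit$params)
  model$fit <- fit["history"]
  r <- cnn_forward(val_stim, model)
  model$val_per_neuron <- colSums(r - Yva * log(r)) / nrow(Yva)
  model
}

# ---- Hyperparameter grid search --------------------------------------------

#' Per-neuron hyperparameter grid search
#'
#' Evaluates every combination of the supplied penalty-strength grids (by
#' default four logarithmically spaced values per grid), fits the model under
#' each configuration, and selects, for each neuron independently, the
#' configuration minimizing its validation Poisson loss. Ties break toward
#' stronger regularization. For readout GLMs the per-neuron selection is
#' exact because neurons are independent given the fixed feature space; the
#' returned model takes each neuron's weights from its winning fit.
#'
#' @param fitter function of one argument (a [reg_config()]) returning a
#'   fitted model with a `val_per_neuron` field (e.g. a closure over
#'   [fit_gfb_glm()] or [fit_lnp()]).
#' @param grids named list of numeric grids over any of `lambda_sparse`,
#'   `lambda_laplace`, `lambda_group`, `lambda_out` (defaults
#'   `10^(-3:0)` for each grid supplied).
#' @param base a [reg_config()] supplying the penalties not searched over.
#' @return list with `best_config` (per-neuron row index into `configs`),
#'   `configs` (data frame of combinations), `val_losses`
#'   (`configs x neurons`), `model` (per-neuron assembled when possible,
#'   otherwise the best-overall fit), and `fits` (all fitted models).
#' @export
grid_search <- function(fitter,
                        grids = list(lambda_sparse = 10^seq(-3, 0)),
                        base = reg_config()) {
  stopifnot(length(grids) >= 1, all(vapply(grids, length, 1L) >= 1))
  if (is.null(names(grids)) || any(!nzchar(names(grids)))) {
    stop("grids must be a named list of penalty grids")
  }
  configs <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  fits <- vector("list", nrow(configs))
  val <- NULL
  for (i in seq_len(nrow(configs))) {
    reg <- base
    for (nm in names(configs)) reg[[nm]] <- configs[i, nm]
    fits[[i]] <- fitter(reg)
    v <- fits[[i]]$val_per_neuron
    if (is.null(v)) stop("fitter result lacks val_per_neuron")
    val <- rbind(val, v)
  }
  strength <- rowSums(log(as.matrix(configs)))
  nn <- ncol(val)
  best <- integer(nn)
  for (j in seq_len(nn)) {
    cand <- which(val[, j] <= min(val[, j]) + 1e-12)
    best[j] <- cand[which.max(strength[cand])]
  }
  model <- fits[[best[1]]]
  if (!is.null(model$W) && length(unique(best)) >= 1) {
    for (j in seq_len(nn)) {
      model$W[, j] <- fits[[best[j]]]$W[, j]
      model$b[j] <- fits[[best[j]]]$b[j]
    }
    model$val_per_neuron <- vapply(seq_len(nn),
                                   function(j) val[best[j], j], numeric(1))
  }
  list(best_config = best, configs = configs, val_losses = val,
       model = model, fits = fits)
}

#' @export
print.lnp_model <- function(x, ...) {
  cat(sprintf("<lnp_model> %d neurons, %d-px pixel filters (exp link)\n",
              ncol(x$W), x$side))
  invisible(x)
}

#' @export
print.gfb_glm_model <- function(x, ...) {
  cat(sprintf(
    "<gfb_glm_model> %d neurons, %d bank features (shifted-ELU output)\n",
    ncol(x$W), nrow(x$W)))
  invisible(x)
}

#' @export
print.pretrained_glm_model <- function(x, ...) {
  cat(sprintf(
    "<pretrained_glm_model> %d neurons reading %s (%s), exp link\n",
    ncol(x$W), x$layer_name, paste(x$shape, collapse = "x")))
  invisible(x)
}
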