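#' Exponential linear unit and its shifted variant
#'
#' `elu(x)` is `x` for `x > 0` and `exp(x) - 1` otherwise. The shifted
#' variant `shifted_elu(x) = elu(x - 1) + 1` is strictly positive and is used
#' as a rate-producing output nonlinearity (`g` in the learned output
#' nonlinearity `f = h * g`).
#'
#' @param x numeric vector/array.
#' @return transformed values, same shape.
#' @export
elu <- function(x) pmax(x, 0) + exp(pmin(x, 0)) - 1

#' @rdname elu
#' @export
shifted_elu <- function(x) pmax(elu(x - 1) + 1, 1e-12)  # floored: exp(x - 1)
                                        # underflows to exactly 0 below -744

# derivatives, used by the trainers; exp(min(x, 0)) is exactly 1 for x > 0
elu_deriv <- function(x) exp(pmin(x, 0))
shifted_elu_deriv <- function(x) elu_deriv(x - 1)

#' Tent (piecewise-linear) basis
#'
#' Uniform grid of interpolation points with triangular basis functions:
#' `t_i(x) = max(0, 1 - |x - x_i| / dx)`. Each `t_i` peaks at 1 on its node,
#' has support `(x_{i-1}, x_{i+1})`, and the family is a partition of unity
#' inside the grid.
#'
#' @param n number of nodes (default 50; together with the default span this
#'   keeps the learned output nonlinearity at 50 parameters per neuron).
#' @param lo,hi grid endpoints (defaults -3 and 6).
#' @return `tent_grid`: list with `x` (nodes) and `dx` (spacing).
#' @export
tent_grid <- function(n = 50L, lo = -3, hi = 6) {
  stopifnot(n >= 2, hi > lo)
  structure(list(x = seq(lo, hi, length.out = n),
                 dx = (hi - lo) / (n - 1)),
            class = "tent_grid")
}

#' @rdname tent_grid
#' @param x evaluation points (any numeric vector).
#' @param grid a [tent_grid()].
#' @return `tent_basis`: `length(x) x n` matrix of basis values.
#' @export
tent_basis <- function(x, grid = tent_grid()) {
  stopifnot(inherits(grid, "tent_grid"))
  u <- outer(as.vector(x), grid$x, function(a, b) abs(a - b) / grid$dx)
  pmax(1 - u, 0)
}

# d t_i / d x; at nodes the subgradient 0 is used
tent_basis_deriv <- function(x, grid = tent_grid()) {
  u <- outer(as.vector(x), grid$x, function(a, b) (a - b) / grid$dx)
  d <- -sign(u) / grid$dx
  d[abs(u) >= 1] <- 0
  d
}

#' Learned output nonlinearity
#'
#' `f(x) = h(x) g(x)` with `h(x) = exp(sum_i alpha_i t_i(x))` a positive
#' piecewise log-linear modulation on the tent grid and `g` the shifted ELU.
#' With all `alpha = 0`, `f` reduces to `g`.
#'
#' @param x drive values.
#' @param alpha coefficients, one per grid node.
#' @param grid a [tent_grid()].
#' @return positive rates, same shape as `x`.
#' @export
output_nonlinearity <- function(x, alpha, grid = tent_grid()) {
  stopifnot(length(alpha) == length(grid$x))
  h <- exp(as.vector(tent_basis(x, grid) %*% alpha))
  out <- h * shifted_elu(as.vector(x))
  dim(out) <- dim(x)
  out
}

#' Dense readout drive
#'
#' Fully connected linear readout over a feature tensor:
#' `sum_ijk Phi_ijk(x) w_ijk + b`.
#'
#' @param features a [feature_tensor()], list of them, or an `n x D` matrix.
#' @param w weight array matching one image's feature shape (or a length-`D`
#'   vector).
#' @param b scalar bias.
#' @return numeric vector, one drive per image.
#' @export
dense_drive <- function(features, w, b = 0) {
  fm <- if (is.matrix(features)) features else flatten_features(features)
  wv <- as.vector(w)
  if (length(wv) != ncol(fm)) {
    stop(sprintf("weight length %d does not match feature dimension %d",
                 length(wv), ncol(fm)))
  }
  as.vector(fm %*% wv + b)
}

#' Factorized readout drive
#'
#' Readout constrained to an outer product of a spatial mask and feature
#' weights, `w_ijk = u_ij v_k`; equals [dense_drive()] with that implied
#' dense weight.
#'
#' @param features a [feature_tensor()] (or `n x h x w x c` array).
#' @param u spatial mask, `h x w`.
#' @param v feature weights, length `c`.
#' @param b scalar bias.
#' @return numeric vector, one drive per image.
#' @export
factorized_drive <- function(features, u, v, b = 0) {
  vals <- if (inherits(features, "feature_tensor")) features$values
          else features
  d <- dim(vals)
  stopifnot(length(d) == 4L, identical(dim(u), d[2:3]), length(v) == d[4])
  w <- as.vector(outer(as.vector(u), as.vector(v)))
  dense_drive(matrix(vals, nrow = d[1]), w, b)
}

#' Linear-nonlinear-Poisson rate
#'
#' One linear filter per input pixel followed by a pointwise exponential:
#' `rate = exp(w . x + b)`.
#'
#' @param images an [image_stack()].
#' @param w pixel filter (`side x side` matrix or flattened vector).
#' @param b scalar bias.
#' @return positive rates, one per image.
#' @export
lnp_rate <- function(images, w, b = 0) {
  stopifnot(inherits(images, "image_stack"))
  xm <- matrix(images$pixels, nrow = n_images(images))
  wv <- as.vector(w)
  if (length(wv) != ncol(xm)) stop("filter does not match the image size")
  as.vector(exp(xm %*% wv + b))
}

#' Feature-GLM rate
#'
#' Dense readout drive passed through a static output nonlinearity: a
#' pointwise exponential for the pretrained-feature GLM, a shifted ELU for
#' the Gabor filter bank GLM.
#'
#' @inheritParams dense_drive
#' @param output `"exp"` or `"shifted_elu"`.
#' @return strictly positive rates, one per image.
#' @export
glm_rate <- function(features, w, b = 0,
                     output = c("exp", "shifted_elu")) {
  output <- match.arg(output)
  drive <- dense_drive(features, w, b)
  if (output == "exp") exp(drive) else shifted_elu(drive)
}

#' Data-driven convolutional core architecture
#'
#' `n_layers` convolutional layers of `channels` feature maps each: a 13x13
#' unpadded first layer, 3x3 zero-padded later layers, each followed by an
#' ELU and (between layers) batch normalization. The default three-layer,
#' 32-channel core maps a 40x40 input to 28x28x32 features.
#'
#' @param n_layers 1--5 convolutional layers (default 3).
#' @param channels feature maps per layer (default 32).
#' @param first_kernel,later_kernel kernel sides (defaults 13 and 3).
#' @return An object of class `cnn_core_spec`.
#' @export
cnn_core_spec <- function(n_layers = 3L, channels = 32L, first_kernel = 13L,
                          later_kernel = 3L) {
  stopifnot(n_layers >= 1, n_layers <= 5, channels >= 1,
            first_kernel >= 1, later_kernel %% 2 == 1)
  structure(list(n_layers = as.integer(n_layers),
                 channels = as.integer(channels),
                 first_kernel = as.integer(first_kernel),
                 later_kernel = as.integer(later_kernel)),
            class = "cnn_core_spec")
}

# spatial side of the core output for a given input side
cnn_output_side <- function(spec, input_side) {
  as.integer(input_side - spec$first_kernel + 1L)  # later layers are padded
}

#' Construct an untrained data-driven CNN model
#'
#' Seeded random initialization of the convolutional core, the per-neuron
#' factorized readouts, and the per-neuron learned output nonlinearities.
#'
#' @param core a [cnn_core_spec()].
#' @param n_neurons number of readout neurons.
#' @param input_side stimulus side in pixels (default 40).
#' @param grid a [tent_grid()] for the output nonlinearities.
#' @param seed integer seed.
#' @return An object of class `cnn_model`.
#' @export
init_cnn_model <- function(core = cnn_core_spec(), n_neurons,
                           input_side = 40L, grid = tent_grid(),
                           seed = 1L) {
  stopifnot(inherits(core, "cnn_core_spec"), n_neurons >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  ch <- core$channels
  conv <- list()
  cin <- 1L
  for (l in seq_len(core$n_layers)) {
    k <- if (l == 1L) core$first_kernel else core$later_kernel
    fan_in <- k^2 * cin
    conv[[l]] <- list(
      w = array(rnorm(k^2 * cin * ch, sd = sqrt(2 / fan_in)),
                dim = c(k, k, cin, ch)),
      b = numeric(ch))
    cin <- ch
  }
  p <- cnn_output_side(core, input_side)
  structure(list(
    core = core, input_side = as.integer(input_side),
    conv = conv,
    u = matrix(rnorm(p * p * n_neurons, sd = 0.1 / p), p * p, n_neurons),
    v = matrix(rnorm(ch * n_neurons, sd = 0.1), ch, n_neurons),
    b = numeric(n_neurons),
    alpha = matrix(0, length(grid$x), n_neurons),
    grid = grid,
    bn = replicate(core$n_layers,
                   list(mean = numeric(ch), var = rep(1, ch)),
                   simplify = FALSE)),
    class = "cnn_model")
}

# core forward pass; mode "train" uses batch statistics (and returns a cache
# for backprop, including the im2col patch matrices, which the backward pass
# reuses), mode "eval" uses the stored running averages. Channel-wise ops are
# done on an (N*h*w) x C matrix view: channels are the trailing dimension, so
# the reshape is copy-cheap and avoids apply()/sweep() overhead.
cnn_core_forward <- function(model, x4, mode = c("eval", "train"),
                             momentum = 0.9) {
  mode <- match.arg(mode)
  spec <- model$core
  train <- mode == "train"
  cache <- list()
  bn_new <- model$bn
  for (l in seq_len(spec$n_layers)) {
    k <- if (l == 1L) spec$first_kernel else spec$later_kernel
    pad <- if (l == 1L) 0L else (k - 1L) %/% 2L
    dx <- dim(x4)
    cols <- im2col_nhwc(x4, k, k, 1L, pad)
    dw <- dim(model$conv[[l]]$w)
    pre <- cols %*% matrix(model$conv[[l]]$w, dw[1] * dw[2] * dw[3], dw[4])
    pre <- pre + rep(model$conv[[l]]$b, each = nrow(pre))
    act <- elu(pre)                        # (N*ho*wo) x C matrix
    ho <- dx[2] + 2L * pad - k + 1L
    wo <- dx[3] + 2L * pad - k + 1L
    if (train) {
      m <- colMeans(act)
      v <- colMeans(act^2) - m^2
      bn_new[[l]]$mean <- momentum * model$bn[[l]]$mean + (1 - momentum) * m
      bn_new[[l]]$var <- momentum * model$bn[[l]]$var + (1 - momentum) * v
    } else {
      m <- model$bn[[l]]$mean
      v <- model$bn[[l]]$var
    }
    nr <- nrow(act)
    s <- sqrt(v + 1e-5)
    out <- (act - rep(m, each = nr)) / rep(s, each = nr)
    cache[[l]] <- list(in_dim = dx, cols = if (train) cols else NULL,
                       pre = pre, act = act, mean = m, var = v,
                       out_dim = c(dx[1], ho, wo, dw[4]))
    x4 <- array(out, dim = c(dx[1], ho, wo, dw[4]))
  }
  list(features = x4, cache = cache, bn = bn_new)
}

#' Forward pass of the data-driven CNN model
#'
#' Runs images through the convolutional core (ELU activations, batch
#' normalization with stored running statistics), applies each neuron's
#' factorized readout, and passes the drive through its learned output
#' nonlinearity.
#'
#' @param images an [image_stack()] of model inputs.
#' @param model a [init_cnn_model()] / fitted `cnn_model`.
#' @return `n_images x n_neurons` matrix of positive rates.
#' @export
cnn_forward <- function(images, model) {
  stopifnot(inherits(images, "image_stack"), inherits(model, "cnn_model"))
  side <- side_px(images)
  if (side != model$input_side) {
    stop(sprintf("model expects %d-px input, got %d", model$input_side, side))
  }
  n <- n_images(images)
  x4 <- array(images$pixels, dim = c(n, side, side, 1L))
  feats <- cnn_core_forward(model, x4, mode = "eval")$features
  drive <- cnn_readout_drive(feats, model)
  rates <- matrix(0, n, ncol(drive))
  for (j in seq_len(ncol(drive))) {
    rates[, j] <- output_nonlinearity(drive[, j], model$alpha[, j],
                                      model$grid)
  }
  rates
}

# factorized drives of all neurons at once: features (n,p,p,c) -> n x n_neur
cnn_readout_drive <- function(feats, model) {
  d <- dim(feats)
  fm <- matrix(feats, nrow = d[1])        # n x (p*p*c), order (h,w,c)
  # dense weights per neuron: vec(u) outer v, flattened in (h*w, c) order
  nn <- ncol(model$u)
  W <- matrix(0, d[2] * d[3] * d[4], nn)
  for (j in seq_len(nn)) {
    W[, j] <- as.vector(outer(model$u[, j], model$v[, j]))
  }
  sweep(fm %*% W, 2, model$b, "+")
}

#' @export
predict_rate.cnn_model <- function(model, images, ...) {
  cnn_forward(images, model)
}

#' Count learned parameters of a model
#'
#' Introspective accounting over the model's trainable tensors, split into
#' the shared core and the per-neuron readout (the convention of the model
#' comparison: batch-normalization running statistics are not learned
#' parameters and the core of the pretrained-feature GLM is its per-channel
#' normalization scale and offset).
#'
#' @param model a fitted or initialized model object.
#' @param n_neurons population size for the total (defaults to the number of
#'   readouts stored in the model).
#' @return `list(core =, readout_per_neuron =, total =)` of integers.
#' @export
count_parameters <- function(model, n_neurons = NULL) {
  UseMethod("count_parameters")
}

#' @export
count_parameters.cnn_model <- function(model, n_neurons = NULL) {
  if (is.null(n_neurons)) n_neurons <- ncol(model$u)
  core <- sum(vapply(model$conv,
                     function(l) length(l$w) + length(l$b), numeric(1)))
  readout <- nrow(model$u) + nrow(model$v) + 1L + nrow(model$alpha)
  list(core = as.integer(core), readout_per_neuron = as.integer(readout),
       total = as.integer(core + n_neurons * readout))
}

#' @export
print.cnn_model <- function(x, ...) {
  cp <- count_parameters(x)
  cat(sprintf(
    "<cnn_model> %d-layer core (%d ch), %d neurons; %d core + %d readout params/neuron\n",
    x$core$n_layers, x$core$channels, ncol(x$u), cp$core,
    cp$readout_per_neuron))
  invisible(x)
}
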