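#' Regularization strengths
#'
#' Penalty weights for readout/filter regularization. Defaults are the
#' cross-validated optima of the model-comparison study this package
#' implements: `lambda_laplace = 0.1`, `lambda_sparse = 0.01`,
#' `lambda_group = 0.001`. `lambda_out` weighs the smoothness penalty of the
#' learned output nonlinearity (no published optimum; default 1).
#'
#' @param lambda_sparse,lambda_laplace,lambda_group,lambda_out nonnegative
#'   penalty strengths.
#' @return An object of class `reg_config`.
#' @export
reg_config <- function(lambda_sparse = 0.01, lambda_laplace = 0.1,
                       lambda_group = 0.001, lambda_out = 1) {
  stopifnot(lambda_sparse >= 0, lambda_laplace >= 0, lambda_group >= 0,
            lambda_out >= 0)
  structure(list(lambda_sparse = lambda_sparse,
                 lambda_laplace = lambda_laplace,
                 lambda_group = lambda_group,
                 lambda_out = lambda_out),
            class = "reg_config")
}

#' Sparsity (L1) penalty
#'
#' `lambda * sum(|w|)`: most readout weights should be zero because spatial
#' pooling is expected to be localized.
#'
#' @param w weights (any shape).
#' @param lambda penalty strength.
#' @return scalar penalty.
#' @export
l1_sparsity <- function(w, lambda) lambda * sum(abs(w))

l1_grad <- function(w, lambda) lambda * sign(w)

# zero-padded same-size cross-correlation with the discrete Laplacian
# L = [[0,-1,0],[-1,4,-1],[0,-1,0]]
laplace_filter <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], matrix(0, 1, nc))
  down <- rbind(matrix(0, 1, nc), m[-nr, , drop = FALSE])
  left <- cbind(m[, -1, drop = FALSE], matrix(0, nr, 1))
  right <- cbind(matrix(0, nr, 1), m[, -nc, drop = FALSE])
  4 * m - up - down - left - right
}

# coerce weights to an (h, w, c) array; a matrix is a single channel
as_hwc <- function(w) {
  if (is.matrix(w)) w <- array(w, dim = c(dim(w), 1L))
  stopifnot(is.array(w), length(dim(w)) == 3L)
  w
}

#' Spatial smoothness penalty (squared Laplacian)
#'
#' `lambda * sum_ijk ((w_:,:,k * L)_ij)^2`, where `*` is zero-padded same-size
#' convolution with the discrete Laplacian kernel. Encourages spatially
#' regular readout weights per feature channel.
#'
#' @param w weights: `h x w` matrix or `h x w x c` array.
#' @param lambda penalty strength.
#' @return scalar penalty.
#' @export
laplacian_smoothness <- function(w, lambda) {
  w <- as_hwc(w)
  tot <- 0
  for (k in seq_len(dim(w)[3])) tot <- tot + sum(laplace_filter(w[, , k])^2)
  lambda * tot
}

# gradient: 2 lambda * L * (L * w) (L is symmetric; zero padding throughout)
laplacian_grad <- function(w, lambda) {
  dw <- dim(w)
  w3 <- as_hwc(w)
  g <- w3
  for (k in seq_len(dim(w3)[3])) {
    g[, , k] <- 2 * lambda * laplace_filter(laplace_filter(w3[, , k]))
  }
  array(g, dim = dw)
}

#' Group sparsity penalty
#'
#' `lambda * sum_k sqrt(sum_ij w_ijk^2)`: an L2 norm per feature channel,
#' summed, encouraging each neuron to pool from a small set of feature maps.
#'
#' @inheritParams laplacian_smoothness
#' @return scalar penalty.
#' @export
group_sparsity <- function(w, lambda) {
  w <- as_hwc(w)
  lambda * sum(sqrt(apply(w^2, 3, sum)))
}

group_grad <- function(w, lambda) {
  dw <- dim(w)
  w3 <- as_hwc(w)
  g <- w3
  for (k in seq_len(dim(w3)[3])) {
    nrm <- sqrt(sum(w3[, , k]^2))
    g[, , k] <- if (nrm > 0) lambda * w3[, , k] / nrm else 0
  }
  array(g, dim = dw)
}

#' Output-nonlinearity smoothness penalty
#'
#' Squared first and second discrete finite differences of the tent-basis
#' coefficients, keeping the learned modulation `h` close to constant and
#' smooth: `lambda * (sum (a_i - a_{i-1})^2 + sum (2 a_i - a_{i-1} - a_{i+1})^2)`.
#'
#' @param alpha coefficient vector.
#' @param lambda penalty strength.
#' @return scalar penalty.
#' @export
output_nl_penalty <- function(alpha, lambda) {
  d1 <- diff(alpha)
  d2 <- diff(alpha, differences = 2)
  lambda * (sum(d1^2) + sum(d2^2))
}

output_nl_grad <- function(alpha, lambda) {
  n <- length(alpha)
  g <- numeric(n)
  d1 <- diff(alpha)
  g[-1] <- g[-1] + 2 * d1
  g[-n] <- g[-n] - 2 * d1
  if (n >= 3) {
    d2 <- diff(alpha, differences = 2)   # d2_i = a_{i+2} - 2 a_{i+1} + a_i
    idx <- seq_len(n - 2)
    g[idx] <- g[idx] + 2 * d2            # note (2a_i - a_{i-1} - a_{i+1})^2
    g[idx + 1] <- g[idx + 1] - 4 * d2    # equals d2^2 up to sign of d2
    g[idx + 2] <- g[idx + 2] + 2 * d2
  }
  lambda * g
}

#' Penalties on the data-driven core's filters
#'
#' Laplacian smoothness on the (single-input-channel) first-layer filters and
#' a group norm over space for every (input channel, output channel) pair of
#' the later layers, encouraging later filters to pool from few feature maps.
#'
#' @param conv list of conv-layer parameter lists `(w, b)` with `w` of shape
#'   `(kh, kw, Cin, Cout)` (as stored in a `cnn_model`).
#' @param reg a [reg_config()].
#' @return scalar penalty.
#' @export
core_filter_penalties <- function(conv, reg) {
  tot <- 0
  for (l in seq_along(conv)) {
    w <- conv[[l]]$w
    d <- dim(w)
    if (l == 1L) {
      tot <- tot + laplacian_smoothness(
        array(w, dim = c(d[1], d[2], d[3] * d[4])), reg$lambda_laplace)
    } else {
      sq <- apply(w^2, c(3, 4), sum)
      tot <- tot + reg$lambda_group * sum(sqrt(sq))
    }
  }
  tot
}

core_filter_grads <- function(conv, reg) {
  lapply(seq_along(conv), function(l) {
    w <- conv[[l]]$w
    d <- dim(w)
    if (l == 1L) {
      g <- laplacian_grad(array(w, dim = c(d[1], d[2], d[3] * d[4])),
                          reg$lambda_laplace)
      array(g, dim = d)
    } else {
      nrm <- sqrt(apply(w^2, c(3, 4), sum))
      nrm[nrm == 0] <- Inf
      w * array(rep(reg$lambda_group / nrm, each = d[1] * d[2]), dim = d)
    }
  })
}
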