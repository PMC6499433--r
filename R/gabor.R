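#' Gabor filter parameters
#'
#' @param sigma scale of the Gaussian envelope, pixels (`> 0`).
#' @param freq spatial frequency of the carrier, cycles per pixel (`> 0`).
#' @param gamma aspect ratio of the envelope, in `(0, 1]`.
#' @param theta orientation, radians in `[0, pi)`.
#' @param phi phase, radians in `[0, 2*pi)`; 0 gives the even (cosine) filter,
#'   `pi/2` the odd (sine) filter of a quadrature pair.
#' @return An object of class `gabor_params`.
#' @export
gabor_params <- function(sigma, freq, gamma = 1, theta = 0, phi = 0) {
  stopifnot(sigma > 0, freq > 0, gamma > 0, gamma <= 1,
            theta >= 0, theta < pi, phi >= 0, phi < 2 * pi)
  structure(list(sigma = sigma, freq = freq, gamma = gamma,
                 theta = theta, phi = phi), class = "gabor_params")
}

#' Evaluate a Gabor kernel
#'
#' Gaussian-windowed sinusoid on a square grid centered at the kernel center:
#' `exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi f x' + phi)` with
#' `(x', y')` the coordinates rotated by `theta`. The kernel side is the
#' minimum of `image_side` and the closest integer to `4 sigma / gamma`.
#'
#' @param p a [gabor_params()].
#' @param image_side side of the image the kernel will be applied to (caps the
#'   kernel size).
#' @return numeric `side x side` matrix; rows index y (image rows), columns x.
#' @export
gabor_kernel <- function(p, image_side = 40L) {
  stopifnot(inherits(p, "gabor_params"))
  side <- min(image_side, round(4 * p$sigma / p$gamma))
  g <- seq_len(side) - (side + 1) / 2
  x <- matrix(g, side, side, byrow = TRUE)   # column offset
  y <- matrix(g, side, side)                 # row offset
  xp <- cos(p$theta) * x - sin(p$theta) * y
  yp <- sin(p$theta) * x + cos(p$theta) * y
  exp(-(xp^2 + p$gamma^2 * yp^2) / (2 * p$sigma^2)) *
    cos(2 * pi * p$freq * xp + p$phi)
}

#' Gabor filter bank configuration
#'
#' The quadrature-pair Gabor filter bank: `N_s` envelope sizes, `N_f` spatial
#' frequencies per size (`f_n = n / (4 sigma)`, i.e. n cycles per envelope
#' width), `N_theta` orientations equally spaced on `[0, pi)`, `N_gamma`
#' aspect ratios (a single aspect ratio means `gamma = 1`; more are equally
#' spaced on `[0.5, 1]`), and one convolution stride shared by all filters.
#'
#' @param sizes_px kernel sides in pixels; `sigma = size / 4` (default
#'   `c(6, 11, 21)`).
#' @param n_freq frequencies per size (default 3).
#' @param n_orient orientations (default 8).
#' @param n_aspect aspect ratios (default 1).
#' @param stride convolution stride in pixels (default 6).
#' @return An object of class `gfb_config`.
#' @export
gfb_config <- function(sizes_px = c(6, 11, 21), n_freq = 3, n_orient = 8,
                       n_aspect = 1, stride = 6) {
  stopifnot(length(sizes_px) >= 1, all(sizes_px >= 1),
            n_freq >= 1, n_orient >= 1, n_aspect >= 1, stride >= 1)
  gammas <- if (n_aspect == 1) 1 else seq(0.5, 1, length.out = n_aspect)
  structure(list(sizes_px = as.integer(sizes_px),
                 sigmas = sizes_px / 4,
                 n_freq = as.integer(n_freq),
                 n_orient = as.integer(n_orient),
                 gammas = gammas,
                 thetas = (seq_len(n_orient) - 1) * pi / n_orient,
                 stride = as.integer(stride)),
            class = "gfb_config")
}

# parameter table of all filter triples for one envelope size
gfb_param_table <- function(cfg, size_index) {
  sigma <- cfg$sigmas[size_index]
  expand.grid(gamma = cfg$gammas,
              freq = (seq_len(cfg$n_freq)) / (4 * sigma),
              theta = cfg$thetas,
              KEEP.OUT.ATTRS = FALSE)
}

#' Gabor filter bank feature maps
#'
#' Convolves each image with every quadrature pair of the bank using valid
#' (no-padding) strided cross-correlation and returns, per filter, the even
#' map `E`, the odd map `O`, and the phase-invariant energy `A = E^2 + O^2`.
#' Envelope sizes produce different spatial output sides
#' (`floor(1 + (side - kernel) / stride)`), so the result is one
#' [feature_tensor()] per size, channels ordered `(E, O, A)` per filter.
#'
#' @param images a preprocessed [image_stack()].
#' @param cfg a [gfb_config()].
#' @return named list of `feature_tensor`s, one per envelope size; flatten
#'   with [flatten_features()] for a readout design matrix.
#' @export
gfb_features <- function(images, cfg = gfb_config()) {
  stopifnot(inherits(images, "image_stack"), inherits(cfg, "gfb_config"))
  side <- side_px(images)
  n <- n_images(images)
  x4 <- array(images$pixels, dim = c(n, side, side, 1L))
  out <- list()
  for (s in seq_along(cfg$sizes_px)) {
    pars <- gfb_param_table(cfg, s)
    k <- min(side, round(4 * cfg$sigmas[s] / pars$gamma[1]))
    # aspect ratios < 1 enlarge the kernel; use the largest needed side
    k <- min(side, max(round(4 * cfg$sigmas[s] / pars$gamma)))
    if (k > side) stop("Gabor kernel larger than the image")
    o <- floor(1 + (side - k) / cfg$stride)
    nf <- nrow(pars)
    kmat <- matrix(0, k * k, 2L * nf)
    for (q in seq_len(nf)) {
      pe <- gabor_params(cfg$sigmas[s], pars$freq[q], pars$gamma[q],
                         pars$theta[q], 0)
      po <- gabor_params(cfg$sigmas[s], pars$freq[q], pars$gamma[q],
                         pars$theta[q], pi / 2)
      # embed (possibly smaller) kernels centered in the k x k support
      kmat[, 2L * q - 1L] <- as.vector(embed_kernel(gabor_kernel(pe, k), k))
      kmat[, 2L * q] <- as.vector(embed_kernel(gabor_kernel(po, k), k))
    }
    cols <- im2col_nhwc(x4, k, k, cfg$stride, 0L)
    eo <- cols %*% kmat                      # (n*o*o) x (2 nf)
    vals <- array(0, dim = c(n, o, o, 3L * nf))
    for (q in seq_len(nf)) {
      e <- array(eo[, 2L * q - 1L], dim = c(n, o, o))
      od <- array(eo[, 2L * q], dim = c(n, o, o))
      vals[, , , 3L * q - 2L] <- e
      vals[, , , 3L * q - 1L] <- od
      vals[, , , 3L * q] <- e^2 + od^2
    }
    labels <- data.frame(
      size_px = cfg$sizes_px[s],
      sigma = cfg$sigmas[s],
      gamma = rep(pars$gamma, each = 3),
      freq = rep(pars$freq, each = 3),
      theta = rep(pars$theta, each = 3),
      type = rep(c("even", "odd", "energy"), nf))
    out[[paste0("size", cfg$sizes_px[s])]] <- feature_tensor(vals, labels)
  }
  out
}

# center a smaller kernel inside a k x k support (zero padding)
embed_kernel <- function(kern, k) {
  ks <- nrow(kern)
  if (ks == k) return(kern)
  out <- matrix(0, k, k)
  off <- floor((k - ks) / 2)
  out[off + seq_len(ks), off + seq_len(ks)] <- kern
  out
}

#' Flattened dimensionality of the Gabor filter bank feature space
#'
#' @param cfg a [gfb_config()].
#' @param side image side in pixels (default 40).
#' @param with_bias add 1 for the readout bias (default `TRUE`, matching the
#'   per-neuron readout parameter count).
#' @return integer dimensionality.
#' @export
gfb_feature_dim <- function(cfg = gfb_config(), side = 40L,
                            with_bias = TRUE) {
  total <- 0L
  for (s in seq_along(cfg$sizes_px)) {
    o <- floor(1 + (side - cfg$sizes_px[s]) / cfg$stride)
    total <- total +
      o^2 * 3L * cfg$n_freq * cfg$n_orient * length(cfg$gammas)
  }
  as.integer(total + as.integer(with_bias))
}
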