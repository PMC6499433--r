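#' Convolutional network topology
#'
#' Ordered layer descriptors for a fixed (pretrained-style) hierarchical
#' feature extractor. Each layer is a list with `name`, `type` (`"conv"` or
#' `"pool"`), and for conv layers `kernel` (odd), `stride`, `pad`, `channels`;
#' pool layers are 2x2 stride-2 max pooling.
#'
#' @param layers list of layer descriptors.
#' @param in_channels channels the network expects at its input (default 3;
#'   grayscale stimuli are replicated).
#' @return An object of class `convnet_spec`.
#' @export
convnet_spec <- function(layers, in_channels = 3L) {
  stopifnot(is.list(layers), length(layers) >= 1)
  for (l in layers) {
    stopifnot(!is.null(l$name), l$type %in% c("conv", "pool"))
    if (l$type == "conv") {
      stopifnot(l$channels >= 1, l$kernel %% 2 == 1)
    }
  }
  nm <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("layer names must be unique")
  structure(list(layers = layers, in_channels = as.integer(in_channels)),
            class = "convnet_spec")
}

conv_layer <- function(name, channels, kernel = 3L, stride = 1L,
                       pad = (kernel - 1L) %/% 2L) {
  list(name = name, type = "conv", channels = as.integer(channels),
       kernel = as.integer(kernel), stride = as.integer(stride),
       pad = as.integer(pad))
}

pool_layer <- function(name) list(name = name, type = "pool")

#' VGG-19-style topology
#'
#' The 16-convolution, five-group topology of the VGG-19 feature extractor
#' (3x3 same-padded convolutions, 2x2 max pooling between groups). Only the
#' topology: weights come from [init_convnet()] (seeded random by default) or
#' an external source.
#'
#' @return A [convnet_spec()].
#' @export
vgg19_spec <- function() {
  ch <- c(64, 128, 256, 512, 512)
  nconv <- c(2, 2, 4, 4, 4)
  layers <- list()
  for (g in 1:5) {
    for (i in seq_len(nconv[g])) {
      layers[[length(layers) + 1L]] <-
        conv_layer(sprintf("conv%d_%d", g, i), ch[g])
    }
    layers[[length(layers) + 1L]] <- pool_layer(sprintf("pool%d", g))
  }
  convnet_spec(layers)
}

#' Initialize convolution weights for a topology
#'
#' He-style normal initialization, deterministic given `seed`. Used as the
#' randomly-initialized stand-in when real pretrained weights are not
#' available; the package's interfaces only require a fixed feature extractor.
#'
#' @param spec a [convnet_spec()].
#' @param seed integer seed.
#' @return list of class `convnet` holding the spec and per-layer weight
#'   arrays `(kh, kw, Cin, Cout)` and biases.
#' @export
init_convnet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "convnet_spec"))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  weights <- list()
  cin <- spec$in_channels
  for (l in spec$layers) {
    if (l$type == "conv") {
      fan_in <- l$kernel^2 * cin
      w <- array(rnorm(l$kernel^2 * cin * l$channels, sd = sqrt(2 / fan_in)),
                 dim = c(l$kernel, l$kernel, cin, l$channels))
      weights[[l$name]] <- list(w = w, b = numeric(l$channels))
      cin <- l$channels
    }
  }
  structure(list(spec = spec, weights = weights), class = "convnet")
}

# strided, padded cross-correlation of an (N,H,W,Cin) array with a
# (kh,kw,Cin,Cout) kernel via im2col + BLAS
conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  dx <- dim(x)
  dw <- dim(w)
  stopifnot(length(dx) == 4L, length(dw) == 4L, dx[4] == dw[3])
  cols <- im2col_nhwc(x, dw[1], dw[2], as.integer(stride), as.integer(pad))
  y <- cols %*% matrix(w, dw[1] * dw[2] * dw[3], dw[4])
  ho <- (dx[2] + 2 * pad - dw[1]) %/% stride + 1
  wo <- (dx[3] + 2 * pad - dw[2]) %/% stride + 1
  y <- array(y, dim = c(dx[1], ho, wo, dw[4]))
  if (!is.null(b)) y <- sweep(y, 4, b, "+")
  y
}

# 2x2 stride-2 max pooling on (N,H,W,C); odd trailing rows/cols are dropped
maxpool2 <- function(x) {
  d <- dim(x)
  ho <- d[2] %/% 2L
  wo <- d[3] %/% 2L
  i <- seq_len(ho) * 2L
  j <- seq_len(wo) * 2L
  pmax(x[, i - 1L, j - 1L, , drop = FALSE], x[, i - 1L, j, , drop = FALSE],
       x[, i, j - 1L, , drop = FALSE], x[, i, j, , drop = FALSE])
}

#' Feature maps of a fixed convolutional network layer
#'
#' Runs the stack of images through the network (grayscale inputs replicated
#' to the channel count the network expects, ReLU after every convolution)
#' and returns the activations of the named convolutional layer *before* its
#' rectifier, as required by the downstream feature normalization.
#'
#' @param images an [image_stack()] of preprocessed stimuli.
#' @param net a `convnet` from [init_convnet()].
#' @param layer_name which convolutional layer to extract (e.g. `"conv3_1"`).
#' @return A [feature_tensor()] `n x h x w x c`.
#' @export
pretrained_features <- function(images, net, layer_name = "conv3_1") {
  stopifnot(inherits(images, "image_stack"), inherits(net, "convnet"))
  spec <- net$spec
  nm <- vapply(spec$layers, `[[`, "", "name")
  if (!layer_name %in% nm) {
    stop(sprintf("unknown layer '%s'; available: %s", layer_name,
                 paste(nm, collapse = ", ")))
  }
  n <- n_images(images)
  side <- side_px(images)
  x <- array(images$pixels, dim = c(n, side, side, 1L))
  x <- array(rep(x, spec$in_channels),
             dim = c(n, side, side, spec$in_channels))
  for (l in spec$layers) {
    if (l$type == "conv") {
      wb <- net$weights[[l$name]]
      x <- conv2d(x, wb$w, wb$b, l$stride, l$pad)
      if (l$name == layer_name) {
        labels <- data.frame(layer = layer_name,
                             channel = seq_len(dim(x)[4]))
        return(feature_tensor(x, labels))
      }
      x[x < 0] <- 0  # ReLU
    } else {
      x <- maxpool2(x)
    }
  }
  stop("unreachable")  # layer_name checked above
}

#' Standardize feature channels, then rectify
#'
#' Normalizes every channel of the (pre-rectifier) feature maps to zero mean
#' and unit variance using statistics pooled over images and spatial
#' positions, applies the learnable per-channel scale and offset, then a
#' ReLU. Standardization keeps an L1 readout penalty comparable across
#' channels. Zero-variance channels fall back to unit scale with a warning.
#'
#' @param features a [feature_tensor()] of pre-rectifier activations.
#' @param stats optional `list(mean, sd)` (length-`c` vectors) from the
#'   training stack; computed from `features` when omitted.
#' @param scale,offset learnable per-channel parameters (default 1 and 0);
#'   `2 * c` parameters in total, exposed via `attr(, "norm_params")`.
#' @return normalized, rectified `feature_tensor`; training statistics in
#'   `attr(, "feature_stats")`.
#' @export
feature_norm <- function(features, stats = NULL, scale = NULL,
                         offset = NULL) {
  stopifnot(inherits(features, "feature_tensor"))
  v <- features$values
  d <- dim(v)
  if (is.null(stats)) {
    m <- apply(v, 4, mean)
    s <- apply(v, 4, sd)
    stats <- list(mean = m, sd = s)
  }
  sdv <- stats$sd
  zerovar <- !is.finite(sdv) | sdv < 1e-12
  if (any(zerovar)) {
    warning(sprintf("%d zero-variance channel(s); unit-scale fallback",
                    sum(zerovar)))
    sdv[zerovar] <- 1
  }
  if (is.null(scale)) scale <- rep(1, d[4])
  if (is.null(offset)) offset <- rep(0, d[4])
  z <- sweep(sweep(v, 4, stats$mean, "-"), 4, sdv, "/")
  z <- sweep(sweep(z, 4, scale, "*"), 4, offset, "+")
  z[z < 0] <- 0
  out <- feature_tensor(z, features$channel_labels)
  attr(out, "feature_stats") <- stats
  attr(out, "norm_params") <- list(scale = scale, offset = offset)
  out
}

#' Theoretical receptive-field size of a network unit
#'
#' Side of the input region influencing one unit of the named layer, by the
#' standard recursive composition (`rf <- rf + (k - 1) * jump`;
#' `jump <- jump * stride`), optionally converted to degrees of visual angle.
#'
#' @param spec a [convnet_spec()].
#' @param layer_name layer at which to stop (inclusive).
#' @param deg_per_px degrees of visual angle per model input pixel (optional).
#' @return `list(px =, degrees =)`; `degrees` is `NULL` when no calibration is
#'   given.
#' @export
receptive_field_size <- function(spec, layer_name, deg_per_px = NULL) {
  stopifnot(inherits(spec, "convnet_spec"))
  nm <- vapply(spec$layers, `[[`, "", "name")
  if (!layer_name %in% nm) {
    stop(sprintf("unknown layer '%s'; available: %s", layer_name,
                 paste(nm, collapse = ", ")))
  }
  rf <- 1
  jump <- 1
  for (l in spec$layers) {
    k <- if (l$type == "conv") l$kernel else 2L
    s <- if (l$type == "conv") l$stride else 2L
    rf <- rf + (k - 1) * jump
    jump <- jump * s
    if (l$name == layer_name) break
  }
  list(px = rf, degrees = if (is.null(deg_per_px)) NULL else rf * deg_per_px)
}
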