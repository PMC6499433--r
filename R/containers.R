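#' Stimulus image stack
#'
#' Container for a stack of square grayscale images together with the display
#' calibration (pixels per degree of visual angle). Images are stored as an
#' `n_images x H x W` numeric array. Before preprocessing, values live on the
#' display intensity scale (0--255); after [crop_resample_zscore()] they are
#' unitless z-scores.
#'
#' @param pixels numeric array `n_images x H x W` (a single `H x W` matrix is
#'   promoted to a one-image stack); all values must be finite.
#' @param px_per_degree pixels per degree of visual angle (default 70, the
#'   display calibration of the experiment the pipeline emulates).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, px_per_degree = 70) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(1L, nrow(pixels), ncol(pixels)))
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  d <- dim(pixels)
  if (d[1] < 1L) stop("image_stack needs at least one image")
  if (d[2] != d[3]) stop("images must be square (H == W)")
  if (!all(is.finite(pixels))) stop("image_stack pixels must all be finite")
  if (!is.numeric(px_per_degree) || length(px_per_degree) != 1L ||
      px_per_degree <= 0) {
    stop("px_per_degree must be a positive scalar")
  }
  structure(list(pixels = pixels, px_per_degree = px_per_degree),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d images, %d x %d px, %.3g px/deg\n",
              d[1], d[2], d[3], x$px_per_degree))
  cat(sprintf("  pixel range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

n_images <- function(images) dim(images$pixels)[1]
side_px <- function(images) dim(images$pixels)[2]

#' Spike-count response block
#'
#' Spike counts per 60-ms bin indexed `(repeat, image, neuron)`, with a
#' logical mask of the same shape flagging valid repeats (sessions differ in
#' how many repetitions each image received).
#'
#' @param counts numeric array `n_reps x n_images x n_neurons`; nonnegative
#'   integers wherever `mask` is `TRUE`.
#' @param mask logical array of the same shape; `TRUE` marks a recorded
#'   repeat. Defaults to all valid.
#' @return An object of class `response_block`.
#' @export
response_block <- function(counts, mask = NULL) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(counts))
  stopifnot(is.logical(mask), identical(dim(mask), dim(counts)))
  valid <- counts[mask]
  if (any(!is.finite(valid)) || any(valid < 0)) {
    stop("counts must be finite and nonnegative where mask is TRUE")
  }
  if (any(abs(valid - round(valid)) > 1e-8)) {
    stop("counts must be integral where mask is TRUE")
  }
  structure(list(counts = counts, mask = mask), class = "response_block")
}

#' @export
print.response_block <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<response_block> %d repeats x %d images x %d neurons (%.1f%% valid)\n",
              d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

#' Per-image feature maps
#'
#' Output of a feature space: an `n_images x h x w x c` array plus per-channel
#' provenance labels (a data frame with one row per channel).
#'
#' @param values numeric 4-d array `n_images x h x w x c`, all finite.
#' @param channel_labels data frame with `c` rows describing each channel.
#' @return An object of class `feature_tensor`.
#' @export
feature_tensor <- function(values, channel_labels = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 4L)
  if (!all(is.finite(values))) stop("feature values must be finite")
  cc <- dim(values)[4]
  if (is.null(channel_labels)) {
    channel_labels <- data.frame(channel = seq_len(cc))
  }
  if (nrow(channel_labels) != cc) {
    stop("channel_labels must have one row per channel")
  }
  structure(list(values = values, channel_labels = channel_labels),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_tensor> %d images, %d x %d x %d\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Flatten features to a design matrix
#'
#' Flattens a [feature_tensor()] (or a list of them, e.g. the multi-size
#' output of [gfb_features()]) into an `n_images x D` matrix whose column
#' order is R's native array order `(h, w, c)` per tensor, tensors
#' concatenated in list order.
#'
#' @param features a `feature_tensor` or list of `feature_tensor`s.
#' @return numeric matrix `n_images x D`.
#' @export
flatten_features <- function(features) {
  if (inherits(features, "feature_tensor")) features <- list(features)
  mats <- lapply(features, function(ft) {
    d <- dim(ft$values)
    matrix(ft$values, nrow = d[1])
  })
  do.call(cbind, mats)
}
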