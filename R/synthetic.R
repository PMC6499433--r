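#' Generate naturalistic noise stimuli
#'
#' Gaussian noise images with amplitude spectrum proportional to
#' `1/f^beta` (`beta = 0` white, `beta` near 1 natural-image-like), scaled to
#' the display intensity range and contrast-matched with [contrast_match()].
#' Stands in for the grayscale photographs and synthesized textures used in
#' the recordings the package emulates.
#'
#' @param n_images number of images (`>= 1`).
#' @param side_px image side in pixels (default 80, matching the central crop
#'   of the displayed stimuli).
#' @param spectral_exponent `beta >= 0` of the `1/f^beta` amplitude spectrum
#'   (default 1).
#' @param seed integer seed; same seed, same stack.
#' @param px_per_degree display calibration (default 70).
#' @param contrast_sd nominal pixel standard deviation on the 0--255 scale
#'   before contrast matching (default 30).
#' @param cfg [preprocess_config()] used for contrast matching.
#' @return a contrast-matched [image_stack()] on the intensity scale.
#' @export
generate_stimuli <- function(n_images, side_px = 80L, spectral_exponent = 1,
                             seed = 1L, px_per_degree = 70,
                             contrast_sd = 30, cfg = preprocess_config()) {
  stopifnot(n_images >= 1, side_px >= 4, spectral_exponent >= 0)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n <- as.integer(side_px)
  fx <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  f <- sqrt(outer(fx^2, fx^2, "+"))
  amp <- f
  amp[f > 0] <- 1 / f[f > 0]^spectral_exponent
  amp[f == 0] <- 0  # zero DC; the mean is set by contrast matching
  px <- array(0, dim = c(n_images, n, n))
  for (i in seq_len(n_images)) {
    z <- matrix(rnorm(n * n), n, n)
    img <- Re(fft(fft(z) * amp, inverse = TRUE)) / (n * n)
    img <- (img - mean(img)) / max(sd(as.vector(img)), 1e-12)
    px[i, , ] <- 128 + contrast_sd * img
  }
  contrast_match(image_stack(px, px_per_degree), cfg)
}

#' Ground-truth synthetic neuron
#'
#' Specification of one simulated V1 neuron: a phase-sensitive rectified
#' linear (`simple`) or quadrature-pair energy (`complex`) function of the
#' stimulus, built on a preferred Gabor filter, plus a gain and a baseline
#' rate. Rates are spikes per 60-ms bin.
#'
#' @param cell_type `"simple"` or `"complex"`.
#' @param gabor a [gabor_params()] describing the preferred filter (its `phi`
#'   is the simple cell's preferred phase; complex cells use the quadrature
#'   pair at phases 0 and `pi/2`).
#' @param gain spikes per bin per unit drive (`> 0`). Filters are normalized
#'   to unit L2 norm, so for z-scored stimuli the linear drive has roughly
#'   unit scale.
#' @param baseline spikes per bin added to every response (`>= 0`).
#' @param center receptive-field center offset from the image center,
#'   `c(row, col)` pixels.
#' @return An object of class `synthetic_neuron`.
#' @export
synthetic_neuron <- function(cell_type = c("simple", "complex"), gabor,
                             gain = 1, baseline = 0.1, center = c(0, 0)) {
  cell_type <- match.arg(cell_type)
  stopifnot(inherits(gabor, "gabor_params"), gain > 0, baseline >= 0,
            length(center) == 2)
  structure(list(cell_type = cell_type, gabor = gabor, gain = gain,
                 baseline = baseline, center = center),
            class = "synthetic_neuron")
}

# unit-norm quadrature filter pair of a neuron, embedded at its center
# position in a side x side image
neuron_filters <- function(spec, side) {
  place <- function(phi) {
    p <- spec$gabor
    kern <- gabor_kernel(gabor_params(p$sigma, p$freq, p$gamma, p$theta, phi),
                         side)
    k <- nrow(kern)
    out <- matrix(0, side, side)
    r0 <- floor((side - k) / 2) + round(spec$center[1])
    c0 <- floor((side - k) / 2) + round(spec$center[2])
    if (r0 < 0 || c0 < 0 || r0 + k > side || c0 + k > side) {
      stop("neuron filter (with center offset) does not fit in the image")
    }
    out[r0 + seq_len(k), c0 + seq_len(k)] <- kern
    out / sqrt(sum(out^2))
  }
  if (spec$cell_type == "simple") {
    list(even = place(spec$gabor$phi))
  } else {
    list(even = place(0), odd = place(pi / 2))
  }
}

#' Noise-free firing rate of a synthetic neuron
#'
#' Simple cells: `rate = baseline + gain * max(0, w_even . x)` (half-wave
#' rectified linear). Complex cells:
#' `rate = baseline + gain * ((w_even . x)^2 + (w_odd . x)^2)` (quadrature
#' energy). Filters have unit L2 norm.
#'
#' @param spec a [synthetic_neuron()].
#' @param images an [image_stack()] of (z-scored) model inputs.
#' @return numeric vector of rates (spikes per bin), one per image; always
#'   `>= baseline`.
#' @export
ground_truth_rate <- function(spec, images) {
  stopifnot(inherits(spec, "synthetic_neuron"),
            inherits(images, "image_stack"))
  side <- side_px(images)
  filt <- neuron_filters(spec, side)
  xm <- matrix(images$pixels, nrow = n_images(images))  # n x (side*side)
  if (spec$cell_type == "simple") {
    drive <- pmax(0, xm %*% as.vector(filt$even))
  } else {
    drive <- (xm %*% as.vector(filt$even))^2 + (xm %*% as.vector(filt$odd))^2
  }
  as.vector(spec$baseline + spec$gain * drive)
}

#' @export
predict_rate.synthetic_neuron <- function(model, images, ...) {
  ground_truth_rate(model, images)
}

#' @export
predict_rate.list <- function(model, images, ...) {
  # a population: one column of rates per member
  vapply(model, predict_rate, numeric(n_images(images)), images = images)
}

#' Predicted firing rates of a model
#'
#' Generic stimulus-to-rate interface shared by all model families (and by
#' ground-truth synthetic neurons), used by the evaluation and in-silico
#' tuning machinery.
#'
#' @param model a fitted model object or a [synthetic_neuron()].
#' @param images an [image_stack()] of model inputs.
#' @param ... passed to methods.
#' @return rates: a vector (single neuron) or `n_images x n_neurons` matrix.
#' @export
predict_rate <- function(model, images, ...) UseMethod("predict_rate")

#' Sample a synthetic population
#'
#' Draws `n_neurons` ground-truth neurons with orientations uniform on
#' `[0, pi)`, envelope scales, frequencies (in cycles per envelope width),
#' gains and baselines uniform (gains log-uniform) within the given ranges,
#' and receptive-field centers jittered around the image center. Complex-cell
#' gains are halved relative to simple cells because the energy drive has
#' roughly twice the scale of a rectified linear drive. Defaults give
#' explainable-variance ratios spanning the 0.15 inclusion threshold and mean
#' rates of order 1 spike per 60-ms bin.
#'
#' @param n_neurons population size (default 166, the size of the recorded
#'   population the generator emulates).
#' @param fraction_complex fraction of energy-model neurons, in `[0, 1]`
#'   (default 0.5).
#' @param sigma_range envelope scale range, pixels (default `c(2, 4)` at the
#'   40-px input scale).
#' @param cycles_range cycles per envelope width (`4 sigma`), so frequency is
#'   `cycles / (4 sigma)` (default `c(1, 2.5)`).
#' @param gain_range simple-cell gain range, spikes per bin per unit drive
#'   (default `c(0.3, 3)`, log-uniform).
#' @param baseline_range baseline range, spikes per bin (default
#'   `c(0.05, 0.3)`).
#' @param center_jitter_px maximal receptive-field center offset (default 5).
#' @param seed integer seed.
#' @return list of [synthetic_neuron()]s.
#' @export
make_population <- function(n_neurons = 166L, fraction_complex = 0.5,
                            sigma_range = c(2, 4), cycles_range = c(1, 2.5),
                            gain_range = c(0.3, 3),
                            baseline_range = c(0.05, 0.3),
                            center_jitter_px = 5, seed = 1L) {
  if (fraction_complex < 0 || fraction_complex > 1) {
    stop("fraction_complex must be in [0, 1]")
  }
  stopifnot(n_neurons >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n_complex <- round(n_neurons * fraction_complex)
  types <- rep(c("complex", "simple"),
               c(n_complex, n_neurons - n_complex))
  lapply(seq_len(n_neurons), function(i) {
    sigma <- runif(1, sigma_range[1], sigma_range[2])
    cyc <- runif(1, cycles_range[1], cycles_range[2])
    gain <- exp(runif(1, log(gain_range[1]), log(gain_range[2])))
    if (types[i] == "complex") gain <- gain / 2
    synthetic_neuron(
      cell_type = types[i],
      gabor = gabor_params(sigma = sigma, freq = cyc / (4 * sigma),
                           gamma = 1, theta = runif(1, 0, pi),
                           phi = runif(1, 0, 2 * pi)),
      gain = gain,
      baseline = runif(1, baseline_range[1], baseline_range[2]),
      center = round(runif(2, -center_jitter_px, center_jitter_px)))
  })
}

#' Poisson trial-to-trial variability
#'
#' Draws independent Poisson spike counts for every repeat of every
#' (image, neuron) rate.
#'
#' @param rates `n_images x n_neurons` matrix (or vector for one neuron) of
#'   nonnegative rates, spikes per bin.
#' @param n_reps repeats per image (default 4).
#' @param seed integer seed.
#' @param mask optional logical `n_reps x n_images x n_neurons` validity mask.
#' @return a [response_block()].
#' @export
sample_responses <- function(rates, n_reps = 4L, seed = 1L, mask = NULL) {
  if (is.vector(rates)) rates <- matrix(rates, ncol = 1)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates must be finite and nonnegative")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  ni <- nrow(rates)
  nn <- ncol(rates)
  counts <- array(rpois(n_reps * ni * nn,
                        lambda = rep(rates, each = n_reps)),
                  dim = c(n_reps, ni, nn))
  response_block(counts, mask)
}

#' Train/validation/test split
#'
#' 80/20 train/test split, then 20% of the training images held out for
#' validation: proportions 64/16/20 of the full set. Disjoint, exhaustive,
#' deterministic given `seed`.
#'
#' @param n_images number of images.
#' @param seed integer seed.
#' @return `list(train =, validation =, test =)` of image indices.
#' @export
split_dataset <- function(n_images, seed = 1L) {
  stopifnot(n_images >= 3)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  perm <- sample.int(n_images)
  n_test <- round(0.2 * n_images)
  test <- perm[seq_len(n_test)]
  rest <- perm[-seq_len(n_test)]
  n_val <- round(0.2 * length(rest))
  validation <- rest[seq_len(n_val)]
  train <- rest[-seq_len(n_val)]
  list(train = sort(train), validation = sort(validation),
       test = sort(test))
}

#' Simulate a complete synthetic recording
#'
#' End-to-end convenience: generates `1/f`-spectrum stimuli, preprocesses them
#' into z-scored model inputs, samples a ground-truth population, computes
#' noise-free rates and Poisson responses, and splits the images.
#'
#' @param n_images number of stimuli.
#' @param population list of [synthetic_neuron()]s, or `NULL` to draw one via
#'   [make_population()] with `...`.
#' @param n_reps repeats per image (default 4; the recordings emulated here
#'   had 2--4).
#' @param spectral_exponent stimulus `1/f^beta` exponent (default 1).
#' @param seed integer master seed; stimulus, population and response seeds
#'   are derived from it.
#' @param cfg a [preprocess_config()].
#' @param ... forwarded to [make_population()] when `population` is `NULL`.
#' @return list with `stimuli` (z-scored 40-px [image_stack()]), `responses`
#'   (a [response_block()]), `splits`, `population`, `rates`
#'   (`n_images x n_neurons` ground truth), and `zscore_stats`.
#' @export
simulate_dataset <- function(n_images = 1000L, population = NULL,
                             n_reps = 4L, spectral_exponent = 1, seed = 1L,
                             cfg = preprocess_config(), ...) {
  raw <- generate_stimuli(n_images, side_px = cfg$crop_px,
                          spectral_exponent = spectral_exponent,
                          seed = seed, cfg = cfg)
  stim <- crop_resample_zscore(apply_mask(raw, cfg), cfg)
  if (is.null(population)) {
    population <- make_population(seed = seed + 1000L, ...)
  }
  rates <- vapply(population, ground_truth_rate, numeric(n_images),
                  images = stim)
  responses <- sample_responses(rates, n_reps = n_reps, seed = seed + 2000L)
  splits <- split_dataset(n_images, seed = seed + 3000L)
  list(stimuli = stim, responses = responses, splits = splits,
       population = population, rates = rates,
       zscore_stats = attr(stim, "zscore_stats"))
}

#' Write / read a simulated dataset
#'
#' Serializes the dataset list from [simulate_dataset()] to a single RDS
#' archive (an HDF5 layout was considered, but no HDF5 binding ships with the
#' supported R installation).
#'
#' @param dataset list from [simulate_dataset()].
#' @param path file path.
#' @return `path` (write) or the dataset list (read).
#' @export
write_dataset <- function(dataset, path) {
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) readRDS(path)
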