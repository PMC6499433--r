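#' Parametric Gabor probe grid
#'
#' Grid of Gabor-patch stimuli (the size of the model input) used to probe a
#' fitted stimulus-to-rate model: orientations on `[0, pi)`, log-spaced
#' spatial frequencies within the stimulus band, phases on `[0, 2 pi)`.
#'
#' @param side probe image side in pixels (default 40, the model input).
#' @param n_orient,n_freq,n_phase grid densities (defaults 16, 8, 8).
#' @param freq_range probe spatial-frequency band in cycles per pixel
#'   (default `c(0.04, 0.32)`, covering the synthetic population band).
#' @param sigma_px envelope scale of the probe patch; the default `side / 4`
#'   makes the patch fill the stimulus like the experiment's probes.
#' @param amplitude probe contrast on the display intensity scale
#'   (default 60).
#' @param px_per_degree calibration of the probe images (default 35, the
#'   40-px model input after 2x subsampling of a 70 px/deg display).
#' @return An object of class `probe_grid`.
#' @export
probe_grid <- function(side = 40L, n_orient = 16L, n_freq = 8L,
                       n_phase = 8L, freq_range = c(0.04, 0.32),
                       sigma_px = side / 4, amplitude = 60,
                       px_per_degree = 35) {
  stopifnot(n_orient >= 1, n_freq >= 1, n_phase >= 1,
            freq_range[1] > 0, freq_range[2] > freq_range[1])
  structure(list(
    side = as.integer(side),
    orientations = (seq_len(n_orient) - 1) * pi / n_orient,
    freqs = exp(seq(log(freq_range[1]), log(freq_range[2]),
                    length.out = n_freq)),
    phases = (seq_len(n_phase) - 1) * 2 * pi / n_phase,
    sigma_px = sigma_px, amplitude = amplitude,
    px_per_degree = px_per_degree),
    class = "probe_grid")
}

# full stack of probe images on the display intensity scale, ordered with
# orientation fastest, then frequency, then phase
probe_stimuli <- function(grid) {
  combos <- expand.grid(theta = grid$orientations, freq = grid$freqs,
                        phi = grid$phases, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(combos)
  px <- array(0, dim = c(n, grid$side, grid$side))
  g <- seq_len(grid$side) - (grid$side + 1) / 2
  x <- matrix(g, grid$side, grid$side, byrow = TRUE)
  y <- matrix(g, grid$side, grid$side)
  for (i in seq_len(n)) {
    th <- combos$theta[i]
    xp <- cos(th) * x - sin(th) * y
    yp <- sin(th) * x + cos(th) * y
    patch <- exp(-(xp^2 + yp^2) / (2 * grid$sigma_px^2)) *
      cos(2 * pi * combos$freq[i] * xp + combos$phi[i])
    px[i, , ] <- 128 + grid$amplitude * patch
  }
  image_stack(px, grid$px_per_degree)
}

#' Probe a model with parametric Gabor stimuli
#'
#' Generates the probe stack, passes it through the same preprocessing as the
#' training stimuli (cosine mask, then z-scoring with the training
#' statistics), and evaluates the model on every probe.
#'
#' @param model anything with a [predict_rate()] method (fitted model or
#'   ground-truth [synthetic_neuron()]).
#' @param grid a [probe_grid()].
#' @param zscore_stats the training-set z-scoring statistics
#'   (`list(mean, sd)`); when `NULL` the probes are z-scored by their own
#'   statistics.
#' @param cfg [preprocess_config()] controlling the mask geometry.
#' @return rate array `n_orient x n_freq x n_phase x n_neurons`.
#' @export
probe_responses <- function(model, grid = probe_grid(), zscore_stats = NULL,
                            cfg = preprocess_config()) {
  stopifnot(inherits(grid, "probe_grid"))
  probes <- probe_stimuli(grid)
  pcfg <- preprocess_config(
    target_mean = cfg$target_mean,
    match_region_px = min(cfg$match_region_px, grid$side),
    mask_diameter_deg = cfg$mask_diameter_deg,
    fade_start_deg = cfg$fade_start_deg,
    crop_px = grid$side, out_px = grid$side)
  probes <- crop_resample_zscore(apply_mask(probes, pcfg), pcfg,
                                 stats = zscore_stats)
  r <- predict_rate(model, probes)
  if (is.vector(r)) r <- matrix(r, ncol = 1)
  array(r, dim = c(length(grid$orientations), length(grid$freqs),
                   length(grid$phases), ncol(r)))
}

# pick the slice (over the last kept axes) maximizing the response range
# along the tuning axis
best_slice <- function(rates3, axis) {
  d <- dim(rates3)
  other <- setdiff(1:3, axis)
  rng <- apply(rates3, other, function(v) diff(range(v)))
  idx <- which(rng == max(rng), arr.ind = TRUE)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = length(other))
  idx[1, ]
}

#' Orientation tuning from probe responses
#'
#' Slices the probe-rate tensor at the spatial frequency and phase maximizing
#' the response range over orientation, fits the axial (pi-periodic) von
#' Mises tuning curve `r(theta) = A exp(kappa cos 2(theta - theta0)) + c` by
#' least squares, and computes the full width at half maximum of the fitted
#' curve analytically: `FWHM = acos(log(cosh(kappa)) / kappa)` (in units of
#' `2 theta`), converted to degrees.
#'
#' @param rates `n_orient x n_freq x n_phase` array for one neuron (one slice
#'   of [probe_responses()] output).
#' @param grid the [probe_grid()] that generated the rates.
#' @return `list(theta, curve, params (A, kappa, theta0, c), fwhm_deg,
#'   pref_theta, flagged)`; `flagged = TRUE` (with `fwhm_deg = NA`) when the
#'   curve is flat or the fit failed.
#' @export
orientation_tuning <- function(rates, grid = probe_grid()) {
  stopifnot(length(dim(rates)) == 3L)
  sl <- best_slice(rates, 1L)
  curve <- rates[, sl[1], sl[2]]
  theta <- grid$orientations
  flat <- diff(range(curve)) < 1e-8 * max(mean(curve), 1e-12)
  if (flat) {
    return(list(theta = theta, curve = curve, params = NULL,
                fwhm_deg = NA_real_, pref_theta = NA_real_, flagged = TRUE))
  }
  th0_init <- theta[which.max(curve)]
  sse <- function(par) {
    kappa <- exp(par[1])
    th0 <- par[2]
    basis <- exp(kappa * cos(2 * (theta - th0)))
    cf <- tryCatch(stats::lm.fit(cbind(basis, 1), curve)$coefficients,
                   error = function(e) c(NA, NA))
    if (any(!is.finite(cf))) return(1e30)
    sum((cf[1] * basis + cf[2] - curve)^2)
  }
  opt <- tryCatch(
    optim(c(log(2), th0_init), sse, method = "Nelder-Mead",
          control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) {
    return(list(theta = theta, curve = curve, params = NULL,
                fwhm_deg = NA_real_, pref_theta = NA_real_, flagged = TRUE))
  }
  kappa <- exp(opt$par[1])
  th0 <- opt$par[2] %% pi
  basis <- exp(kappa * cos(2 * (theta - th0)))
  cf <- stats::lm.fit(cbind(basis, 1), curve)$coefficients
  A <- cf[1]
  cc <- cf[2]
  if (!is.finite(A) || A <= 0) {
    return(list(theta = theta, curve = curve, params = NULL,
                fwhm_deg = NA_real_, pref_theta = NA_real_, flagged = TRUE))
  }
  # half maximum of the modulated component: exp(kappa cos 2 d) = cosh(kappa)
  ratio <- log(cosh(kappa)) / kappa
  fwhm <- if (ratio >= 1) NA_real_ else 2 * (acos(ratio) / 2) * 180 / pi
  list(theta = theta, curve = curve,
       params = list(A = unname(A), kappa = kappa, theta0 = th0,
                     c = unname(cc)),
       fwhm_deg = fwhm, pref_theta = th0, flagged = !is.finite(fwhm))
}

#' Phase tuning and the simple-complex linearity index
#'
#' Slices the probe-rate tensor at the spatial frequency and orientation
#' maximizing the response range over phase and fits the cosine tuning curve
#' `r(phi) = a cos(phi - phi0) + c` by linear least squares. The linearity
#' index is `a / c` clipped to `[0, 1]`: near 0 for phase-invariant
#' (complex) cells, near 1 for phase-sensitive (simple) cells.
#'
#' @inheritParams orientation_tuning
#' @return `list(phi, curve, params (a, phi0, c), linearity, linearity_raw,
#'   flagged)`; `flagged = TRUE` when the fitted offset is not positive.
#' @export
phase_tuning <- function(rates, grid = probe_grid()) {
  stopifnot(length(dim(rates)) == 3L)
  sl <- best_slice(rates, 3L)
  curve <- rates[sl[1], sl[2], ]
  phi <- grid$phases
  cf <- stats::lm.fit(cbind(1, cos(phi), sin(phi)), curve)$coefficients
  a <- sqrt(cf[2]^2 + cf[3]^2)
  cc <- cf[1]
  phi0 <- atan2(cf[3], cf[2]) %% (2 * pi)
  if (!is.finite(cc) || cc <= 0) {
    return(list(phi = phi, curve = curve,
                params = list(a = unname(a), phi0 = phi0, c = unname(cc)),
                linearity = NA_real_, linearity_raw = NA_real_,
                flagged = TRUE))
  }
  raw <- unname(a / cc)
  list(phi = phi, curve = curve,
       params = list(a = unname(a), phi0 = phi0, c = unname(cc)),
       linearity = min(max(raw, 0), 1), linearity_raw = raw,
       flagged = FALSE)
}

#' Classify neurons on the simple-complex axis
#'
#' Thresholds on the linearity index: `> 0.3` simple, `< 0.04` complex,
#' otherwise unclassified.
#'
#' @param linearity numeric vector of linearity indices.
#' @return character vector: `"simple"`, `"complex"`, or `"unclassified"`
#'   (`NA` input stays `NA`).
#' @export
classify_simple_complex <- function(linearity) {
  out <- rep(NA_character_, length(linearity))
  ok <- is.finite(linearity)
  out[ok] <- ifelse(linearity[ok] > 0.3, "simple",
                    ifelse(linearity[ok] < 0.04, "complex", "unclassified"))
  out
}

#' In-silico tuning characterization of a model population
#'
#' Probes every model neuron with the Gabor grid and summarizes orientation
#' tuning (preferred orientation, FWHM) and phase tuning (linearity index and
#' simple/complex label) per neuron.
#'
#' @inheritParams probe_responses
#' @return data frame with one row per neuron: `pref_theta_deg`, `fwhm_deg`,
#'   `linearity`, `linearity_raw`, `label`, `flagged`.
#' @export
tuning_analysis <- function(model, grid = probe_grid(), zscore_stats = NULL,
                            cfg = preprocess_config()) {
  rt <- probe_responses(model, grid, zscore_stats, cfg)
  nn <- dim(rt)[4]
  rows <- lapply(seq_len(nn), function(j) {
    r3 <- rt[, , , j]
    dim(r3) <- dim(rt)[1:3]
    ot <- orientation_tuning(r3, grid)
    pt <- phase_tuning(r3, grid)
    data.frame(neuron = j,
               pref_theta_deg = if (is.na(ot$pref_theta)) NA_real_
                                else ot$pref_theta * 180 / pi,
               fwhm_deg = ot$fwhm_deg,
               linearity = pt$linearity,
               linearity_raw = pt$linearity_raw,
               label = classify_simple_complex(pt$linearity),
               flagged = ot$flagged || pt$flagged)
  })
  do.call(rbind, rows)
}
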