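#' Preprocessing configuration
#'
#' Parameters of the stimulus conditioning pipeline: contrast matching of the
#' central unmasked region, the circular cosine-fade mask, and the
#' crop/resample/z-score step that produces model inputs.
#'
#' @param target_mean display intensity the match region is centered on
#'   (default 128, the gray background).
#' @param match_region_px diameter in pixels of the central disc used for
#'   contrast matching (default 70 = 1 degree at 70 px/deg).
#' @param mask_diameter_deg outer diameter of the circular mask in degrees
#'   (default 2).
#' @param fade_start_deg diameter at which the cosine fade begins, degrees
#'   (default 1).
#' @param crop_px side of the central crop taken before resampling
#'   (default 80).
#' @param out_px side of the model input after resampling (default 40).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_mean = 128, match_region_px = 70,
                              mask_diameter_deg = 2, fade_start_deg = 1,
                              crop_px = 80, out_px = 40) {
  stopifnot(target_mean > 0, match_region_px > 0,
            fade_start_deg > 0, fade_start_deg < mask_diameter_deg,
            out_px >= 1, out_px <= crop_px)
  structure(list(target_mean = target_mean,
                 match_region_px = match_region_px,
                 mask_diameter_deg = mask_diameter_deg,
                 fade_start_deg = fade_start_deg,
                 crop_px = crop_px, out_px = out_px),
            class = "preprocess_config")
}

# radial distance of every pixel from the image center, in pixels
radial_px <- function(side) {
  ctr <- (side + 1) / 2
  g <- seq_len(side) - ctr
  sqrt(outer(g^2, g^2, "+"))
}

# disc membership for the central matching region
match_region_mask <- function(side, diameter_px) {
  radial_px(side) <= diameter_px / 2
}

#' Contrast-match a stimulus stack
#'
#' Rescales each image so that the central, unmasked matching disc has mean
#' `target_mean` and standard deviation equal to the across-image average of
#' the pre-rescaling disc standard deviations; pixels leaving \[0, 255\] are
#' clipped afterwards.
#'
#' @param images an [image_stack()] on the display intensity scale.
#' @param cfg a [preprocess_config()].
#' @return A contrast-matched `image_stack`.
#' @export
contrast_match <- function(images, cfg = preprocess_config()) {
  stopifnot(inherits(images, "image_stack"),
            inherits(cfg, "preprocess_config"))
  px <- images$pixels
  side <- side_px(images)
  disc <- match_region_mask(side, cfg$match_region_px)
  n <- n_images(images)
  mu <- numeric(n)
  sg <- numeric(n)
  for (i in seq_len(n)) {
    v <- px[i, , ][disc]
    mu[i] <- mean(v)
    sg[i] <- sd(v)
  }
  bad <- which(sg < 1e-12)
  if (length(bad)) {
    stop(sprintf("zero variance inside the matching region for image(s): %s",
                 paste(bad, collapse = ", ")))
  }
  target_sd <- mean(sg)
  out <- px
  for (i in seq_len(n)) {
    out[i, , ] <- (px[i, , ] - mu[i]) * (target_sd / sg[i]) + cfg$target_mean
  }
  out[out < 0] <- 0
  out[out > 255] <- 255
  image_stack(out, images$px_per_degree)
}

#' Circular cosine-fade mask profile
#'
#' Radial weight of the stimulus mask: 1 inside a 1-degree diameter, a half
#' cosine fade between 0.5 and 1 degree radius, 0 outside the 2-degree
#' diameter. `r` is the radial distance from the mask center in degrees.
#'
#' @param r radial distance(s) in degrees, all `>= 0`.
#' @return weight(s) in \[0, 1\], continuous in `r`.
#' @export
cosine_mask_value <- function(r) {
  if (any(r < 0)) stop("radial distance must be nonnegative")
  mask_weight(r, fade_start_r = 0.5, outer_r = 1)
}

# generalized radial fade: 1 below fade_start_r, half-cosine down to 0 at
# outer_r (radii, same unit as r)
mask_weight <- function(r, fade_start_r, outer_r) {
  w <- numeric(length(r))
  w[r < fade_start_r] <- 1
  fade <- r >= fade_start_r & r < outer_r
  w[fade] <- 0.5 * cos(pi * (r[fade] - fade_start_r) /
                         (outer_r - fade_start_r)) + 0.5
  dim(w) <- dim(r)
  w
}

#' Apply the circular cosine-fade mask
#'
#' Blends every pixel toward the background gray (`cfg$target_mean`) by the
#' mask weight at its radial distance from the image center:
#' `out = mean + m(r) * (in - mean)`.
#'
#' @param images an [image_stack()] with a calibrated `px_per_degree`.
#' @param cfg a [preprocess_config()].
#' @return The masked `image_stack`.
#' @export
apply_mask <- function(images, cfg = preprocess_config()) {
  stopifnot(inherits(images, "image_stack"),
            inherits(cfg, "preprocess_config"))
  side <- side_px(images)
  r_deg <- radial_px(side) / images$px_per_degree
  w <- mask_weight(r_deg, cfg$fade_start_deg / 2, cfg$mask_diameter_deg / 2)
  px <- images$pixels
  for (i in seq_len(n_images(images))) {
    px[i, , ] <- cfg$target_mean + w * (px[i, , ] - cfg$target_mean)
  }
  image_stack(px, images$px_per_degree)
}

# Keys bicubic kernel (a = -0.5), the standard bicubic interpolation weight
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  i2 <- t > 1 & t < 2
  w[i2] <- a * t[i2]^3 - 5 * a * t[i2]^2 + 8 * a * t[i2] - 4 * a
  w
}

# one-dimensional bicubic resampling matrix (n_out x n_in), center-aligned;
# edge samples are clamped and rows renormalized to sum to one
bicubic_matrix <- function(n_in, n_out) {
  scale <- n_in / n_out
  m <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * scale - 0.5        # 0-based source coordinate
    base <- floor(s)
    for (k in -1:2) {
      src <- base + k
      wt <- cubic_kernel(s - src)
      src <- min(max(src, 0), n_in - 1) # clamp to edges
      m[i, src + 1] <- m[i, src + 1] + wt
    }
  }
  sweep(m, 1, rowSums(m), "/")
}

#' Crop, resample and z-score a stimulus stack
#'
#' Extracts the central `crop_px` square, bicubic-resamples it to
#' `out_px x out_px`, and z-scores the result. The z-scoring statistics are a
#' single mean and standard deviation pooled over all pixels of the stack;
#' pass the training-set statistics via `stats` so validation/test splits
#' share the training input scale. The returned stack carries its statistics
#' in `attr(, "zscore_stats")` and a consistently rescaled `px_per_degree`.
#'
#' @param images an [image_stack()].
#' @param cfg a [preprocess_config()].
#' @param stats optional `list(mean =, sd =)` computed on the training stack.
#' @return z-scored `image_stack` of side `out_px`.
#' @export
crop_resample_zscore <- function(images, cfg = preprocess_config(),
                                 stats = NULL) {
  stopifnot(inherits(images, "image_stack"),
            inherits(cfg, "preprocess_config"))
  side <- side_px(images)
  if (cfg$crop_px > side) {
    stop(sprintf("crop (%d px) larger than image (%d px)", cfg$crop_px, side))
  }
  start <- floor((side - cfg$crop_px) / 2) + 1
  idx <- start:(start + cfg$crop_px - 1)
  n <- n_images(images)
  out <- array(0, dim = c(n, cfg$out_px, cfg$out_px))
  if (cfg$out_px == cfg$crop_px) {
    out <- images$pixels[, idx, idx, drop = FALSE]
  } else {
    m <- bicubic_matrix(cfg$crop_px, cfg$out_px)
    for (i in seq_len(n)) {
      out[i, , ] <- m %*% images$pixels[i, idx, idx] %*% t(m)
    }
  }
  if (is.null(stats)) {
    stats <- list(mean = mean(out), sd = sd(as.vector(out)))
  }
  if (!is.finite(stats$sd) || stats$sd < 1e-8) {
    # degenerate (constant) stack: documented policy is an all-zero output
    warning("stack standard deviation below floor; returning all-zero images")
    out[] <- 0
  } else {
    out <- (out - stats$mean) / stats$sd
  }
  res <- image_stack(out, images$px_per_degree * cfg$out_px / cfg$crop_px)
  attr(res, "zscore_stats") <- stats
  res
}

#' Full stimulus preprocessing pipeline
#'
#' Convenience wrapper: [contrast_match()], [apply_mask()], then
#' [crop_resample_zscore()].
#'
#' @inheritParams crop_resample_zscore
#' @return z-scored model-input `image_stack`.
#' @export
preprocess_stimuli <- function(images, cfg = preprocess_config(),
                               stats = NULL) {
  crop_resample_zscore(apply_mask(contrast_match(images, cfg), cfg),
                       cfg, stats)
}

#' Write one image of a stack to PNG for inspection
#'
#' @param images an [image_stack()].
#' @param index which image.
#' @param path output file.
#' @param intensity_range values mapped to black/white; defaults to the image
#'   range.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(images, index, path, intensity_range = NULL) {
  stopifnot(inherits(images, "image_stack"))
  img <- images$pixels[index, , ]
  if (is.null(intensity_range)) intensity_range <- range(img)
  z <- (img - intensity_range[1]) /
    max(intensity_range[2] - intensity_range[1], 1e-12)
  z[z < 0] <- 0
  z[z > 1] <- 1
  grDevices::png(path, width = ncol(img), height = nrow(img))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({graphics::par(op); grDevices::dev.off()}, add = TRUE)
  graphics::image(t(z)[, nrow(z):1], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, useRaster = TRUE)
  invisible(path)
}
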