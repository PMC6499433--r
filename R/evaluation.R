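#' Observation-noise variance per neuron
#'
#' Estimates the trial-to-trial (observation) noise variance by averaging
#' across images the unbiased variance across repetitions of the responses to
#' the same stimulus. Masked repeats are excluded; every image must retain at
#' least two valid repeats.
#'
#' @param block a [response_block()].
#' @return numeric vector, one noise variance per neuron.
#' @export
noise_variance <- function(block) {
  stopifnot(inherits(block, "response_block"))
  d <- dim(block$counts)
  nn <- d[3]
  out <- numeric(nn)
  for (j in seq_len(nn)) {
    nv <- apply(block$mask[, , j], 2, sum)
    short <- which(nv < 2)
    if (length(short)) {
      stop(sprintf(
        "neuron %d: image(s) with fewer than 2 valid repeats: %s",
        j, paste(head(short, 10), collapse = ", ")))
    }
    vars <- vapply(seq_len(d[2]), function(i) {
      y <- block$counts[block$mask[, i, j], i, j]
      var(y)
    }, numeric(1))
    out[j] <- mean(vars)
  }
  out
}

#' Ratio of explainable to total variance
#'
#' `(Var[y] - sigma_noise^2) / Var[y]`, with `Var[y]` the total single-trial
#' response variance (across all valid image-repeat pairs) and the noise
#' variance from [noise_variance()]. Neurons with zero total variance get
#' `NA` with a warning (they cannot enter model evaluation).
#'
#' @param block a [response_block()].
#' @return numeric vector of ratios, one per neuron.
#' @export
explainable_ratio <- function(block) {
  stopifnot(inherits(block, "response_block"))
  sig2 <- noise_variance(block)
  nn <- dim(block$counts)[3]
  out <- numeric(nn)
  for (j in seq_len(nn)) {
    y <- block$counts[, , j][block$mask[, , j]]
    tv <- var(y)
    if (!is.finite(tv) || tv <= 0) {
      warning(sprintf("neuron %d has zero total variance; ratio set to NA", j))
      out[j] <- NA_real_
    } else {
      out[j] <- (tv - sig2[j]) / tv
    }
  }
  out
}

#' Select neurons by explainable-variance ratio
#'
#' Keeps neurons whose [explainable_ratio()] is at least `threshold`
#' (default 0.15, the inclusion criterion of the study this package
#' emulates). `NA` ratios are excluded.
#'
#' @param block a [response_block()].
#' @param threshold minimal ratio (default 0.15).
#' @return integer vector of neuron indices.
#' @export
select_neurons <- function(block, threshold = 0.15) {
  ratio <- suppressWarnings(explainable_ratio(block))
  which(!is.na(ratio) & ratio >= threshold)
}

#' Fraction of explainable variance explained (FEV)
#'
#' `FEV = 1 - (MSE - sigma_noise^2) / (Var[y] - sigma_noise^2)`, where the
#' mean squared error between observed single-trial counts and the model
#' prediction for the corresponding image is taken over all valid
#' image-repeat pairs. A perfect model scores 1 (it cannot explain the
#' observation noise); the grand-mean predictor scores ~0.
#'
#' @param block test-set [response_block()].
#' @param predictions `n_images x n_neurons` matrix (or vector) of predicted
#'   rates aligned with the block's images.
#' @param sigma2 noise variances; estimated from `block` when omitted.
#' @return numeric vector of per-neuron FEV values (each `<= 1`).
#' @export
fev <- function(block, predictions, sigma2 = NULL) {
  stopifnot(inherits(block, "response_block"))
  if (is.vector(predictions)) predictions <- matrix(predictions, ncol = 1)
  d <- dim(block$counts)
  stopifnot(nrow(predictions) == d[2], ncol(predictions) == d[3])
  if (is.null(sigma2)) sigma2 <- noise_variance(block)
  out <- numeric(d[3])
  bad <- integer(0)
  for (j in seq_len(d[3])) {
    msk <- block$mask[, , j]
    y <- block$counts[, , j][msk]
    yhat <- matrix(predictions[, j], d[1], d[2], byrow = TRUE)[msk]
    mse <- mean((y - yhat)^2)
    denom <- var(y) - sigma2[j]
    if (!is.finite(denom) || denom <= 0) {
      bad <- c(bad, j)
      out[j] <- NA_real_
    } else {
      out[j] <- 1 - (mse - sigma2[j]) / denom
    }
  }
  if (length(bad)) {
    stop(sprintf(
      "FEV undefined (explainable variance <= 0) for neuron(s) %s; they should have been excluded",
      paste(bad, collapse = ", ")))
  }
  out
}

#' Population summary of per-neuron scores
#'
#' Arithmetic mean over (included) neurons with a nonparametric bootstrap
#' confidence interval over neurons.
#'
#' @param scores per-neuron values (e.g. FEV).
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return `list(mean =, ci =, n =)`.
#' @export
population_score <- function(scores, level = 0.95, n_boot = 1000L,
                             seed = 1L) {
  scores <- scores[is.finite(scores)]
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n <- length(scores)
  boots <- vapply(seq_len(n_boot),
                  function(i) mean(scores[sample.int(n, replace = TRUE)]),
                  numeric(1))
  a <- (1 - level) / 2
  list(mean = mean(scores),
       ci = unname(quantile(boots, c(a, 1 - a))),
       n = n)
}

#' Pairwise model comparison with Holm correction
#'
#' All pairwise paired Wilcoxon signed-rank tests between the per-neuron
#' score columns, with Holm's step-down adjustment controlling the
#' family-wise error rate at `alpha`.
#'
#' @param fev_table `n_neurons x n_models` matrix (columns named by model).
#' @param alpha family-wise error rate (default 0.05).
#' @return data frame: `model_a`, `model_b`, `p`, `p_adj`, `significant`.
#' @export
compare_models <- function(fev_table, alpha = 0.05) {
  fev_table <- as.matrix(fev_table)
  m <- ncol(fev_table)
  stopifnot(m >= 2)
  if (is.null(colnames(fev_table))) {
    colnames(fev_table) <- paste0("model", seq_len(m))
  }
  pairs <- utils::combn(m, 2)
  res <- data.frame(model_a = colnames(fev_table)[pairs[1, ]],
                    model_b = colnames(fev_table)[pairs[2, ]],
                    p = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    d <- fev_table[, pairs[1, k]] - fev_table[, pairs[2, k]]
    res$p[k] <- if (all(d == 0)) 1 else {
      suppressWarnings(
        wilcox.test(fev_table[, pairs[1, k]], fev_table[, pairs[2, k]],
                    paired = TRUE, exact = FALSE)$p.value)
    }
  }
  res$p_adj <- p.adjust(res$p, method = "holm")
  res$significant <- res$p_adj < alpha
  res
}

#' Spatial energy profile of a dense readout
#'
#' L2 norm of the spatial weights of every feature channel, sorted in
#' descending order, with the cumulative fraction of total readout energy —
#' the summary used to ask how many feature maps a neuron actually pools
#' from.
#'
#' @param w dense readout weights: `h x w x c` array (or a flat vector plus
#'   `shape`).
#' @param shape `c(h, w, c)` when `w` is a vector.
#' @return data frame: `channel`, `energy`, `normalized`, `cumulative`.
#' @export
readout_energy_profile <- function(w, shape = NULL) {
  if (!is.null(shape)) w <- array(w, dim = shape)
  w <- as_hwc(w)
  energy <- sqrt(apply(w^2, 3, sum))
  ord <- order(energy, decreasing = TRUE)
  total <- sum(energy)
  norm <- if (total > 0) energy[ord] / total else energy[ord]
  data.frame(channel = ord, energy = energy[ord], normalized = norm,
             cumulative = cumsum(norm))
}

#' Write per-neuron score tables and a JSON summary
#'
#' @param fev_table `n_neurons x n_models` matrix of per-neuron FEV.
#' @param csv_path per-neuron CSV output.
#' @param json_path JSON summary (per-model mean, CI, pairwise tests).
#' @param seed seed for the bootstrap CIs.
#' @return list with the summary that was written, invisibly.
#' @export
write_scores <- function(fev_table, csv_path, json_path, seed = 1L) {
  fev_table <- as.matrix(fev_table)
  df <- data.frame(neuron = seq_len(nrow(fev_table)), fev_table)
  write.csv(df, csv_path, row.names = FALSE)
  sums <- lapply(seq_len(ncol(fev_table)), function(j) {
    s <- population_score(fev_table[, j], seed = seed)
    list(mean_fev = s$mean, ci = s$ci, n = s$n)
  })
  names(sums) <- colnames(fev_table)
  summary <- list(models = sums, tests = compare_models(fev_table))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
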