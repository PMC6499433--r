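# Small fixture builders shared across test files. All fixtures are built in
# code at test time; nothing is read from disk.

# seeded Gaussian noise stack on the intensity scale
noise_stack <- function(n = 3, side = 40, seed = 1, mean = 128, sd = 25,
                        ppd = 70) {
  set.seed(seed)
  image_stack(array(rnorm(n * side * side, mean, sd), c(n, side, side)), ppd)
}

# a full-field grating stack (one image per phase) on the z-scored scale
grating_stack <- function(theta, freq, phases, side = 40, amp = 1,
                          ppd = 35) {
  g <- seq_len(side) - (side + 1) / 2
  x <- matrix(g, side, side, byrow = TRUE)
  y <- matrix(g, side, side)
  xp <- cos(theta) * x - sin(theta) * y
  px <- array(0, c(length(phases), side, side))
  for (i in seq_along(phases)) {
    px[i, , ] <- amp * cos(2 * pi * freq * xp + phases[i])
  }
  image_stack(px, ppd)
}

# deterministic response block where counts equal an integer rate table over
# all repeats (zero observation noise)
deterministic_block <- function(rates_int, n_reps = 2) {
  ni <- nrow(rates_int)
  nn <- ncol(rates_int)
  counts <- array(0, c(n_reps, ni, nn))
  for (r in seq_len(n_reps)) counts[r, , ] <- rates_int
  response_block(counts)
}

# independent FEV reimplementation used as the oracle in equivalence tests
fev_oracle <- function(counts, mask, predictions) {
  nn <- dim(counts)[3]
  out <- numeric(nn)
  for (j in seq_len(nn)) {
    pervar <- sapply(seq_len(dim(counts)[2]), function(i) {
      stats::var(counts[mask[, i, j], i, j])
    })
    sig2 <- mean(pervar)
    ys <- c()
    yh <- c()
    for (i in seq_len(dim(counts)[2])) {
      yy <- counts[mask[, i, j], i, j]
      ys <- c(ys, yy)
      yh <- c(yh, rep(predictions[i, j], length(yy)))
    }
    out[j] <- 1 - (mean((ys - yh)^2) - sig2) / (stats::var(ys) - sig2)
  }
  out
}
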