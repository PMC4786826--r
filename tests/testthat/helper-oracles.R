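# Independent brute-force oracles. These deliberately avoid the package's
# fft/vectorized code paths: direct O(n^2) DFT sums, elementary trapezoid
# accumulation, window-by-window medians, textbook t statistics and dense
# generalized eigenvalue analysis.

# direct DFT: X[k] = sum_t x[t] exp(-2 pi i k t / n), k = 0..n-1
oracle_dft <- function(x, bins = 0:(length(x) - 1)) {
  n <- length(x)
  vapply(bins, function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
}

oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}

oracle_running_median <- function(x, k) {
  n <- length(x)
  half <- (k - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    w <- sort(x[(i - h):(i + h)])
    m <- length(w)
    out[i] <- if (m %% 2 == 1) w[(m + 1) / 2] else (w[m / 2] + w[m / 2 + 1]) / 2
  }
  out
}

oracle_one_sample_t <- function(d) {
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = tstat, p_value = 2 * pt(-abs(tstat), df = n - 1))
}

# generalized eigenvalues of K v = w^2 M v via dense solve(M) %*% K
oracle_natural_frequencies <- function(model) {
  n <- length(model$masses)
  M <- diag(model$masses, n, n)
  K <- matrix(0, n, n)
  K[1, 1] <- model$ground_stiffness
  if (n > 1) for (i in seq_len(n - 1)) {
    idx <- c(i, i + 1)
    K[idx, idx] <- K[idx, idx] +
      model$stiffnesses[i] * matrix(c(1, -1, -1, 1), 2, 2)
  }
  ev <- eigen(solve(M, K), only.values = TRUE)$values
  sort(sqrt(Re(ev)) / (2 * pi))
}

# dense complex solve of the chain's dynamic stiffness, one frequency at a
# time (cross-checks the vectorized tridiagonal path)
oracle_chain_frf <- function(model, freqs) {
  n <- length(model$masses)
  M <- diag(model$masses, n, n)
  K <- matrix(0, n, n); C <- matrix(0, n, n)
  K[1, 1] <- model$ground_stiffness; C[1, 1] <- model$ground_damping
  if (n > 1) for (i in seq_len(n - 1)) {
    idx <- c(i, i + 1)
    K[idx, idx] <- K[idx, idx] + model$stiffnesses[i] * matrix(c(1, -1, -1, 1), 2, 2)
    C[idx, idx] <- C[idx, idx] + model$dampings[i] * matrix(c(1, -1, -1, 1), 2, 2)
  }
  sens <- if (n == 1) 1 else 2:n
  out <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    x <- solve(K + 1i * w * C - w^2 * M, c(1, rep(0, n - 1)))
    (-w^2 * x[sens]) * model$sensor_attenuation
  }, complex(length(sens)))
  if (is.null(dim(out))) matrix(out, ncol = 1) else t(out)
}

# wrap a vector of per-pair differences as minimal twin_pair_result objects
# (single cell: PEAK at L1) for group-test checks
list_of_single_difference_pairs <- function(d, group = "Discordant") {
  lapply(d, function(di)
    structure(list(pair_id = "P", concordance = group, subjects = c("a", "b"),
                   differences = data.frame(sensor = "L1", outcome = "PEAK",
                                            difference = di,
                                            stringsAsFactors = FALSE)),
              class = "twin_pair_result"))
}

# small noiseless test chain (cheap, sharp modes in-band)
test_chain <- function(noise_rms = 0) {
  spine_model(noise_rms = noise_rms)
}

# short protocol for fast tests: 4 pulses of 0.5 s at 5000 Hz
short_cfg <- function(n_pulses = 4)
  excitation_config(n_pulses = n_pulses, pulse_duration = 0.5)

# analysis band for the short protocol (2 Hz grid)
short_band <- c(2, 2000)
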