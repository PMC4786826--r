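#' Excitation configuration
#'
#' Parameters of the pulse-train excitation delivered by the shaker at T12:
#' a train of `n_pulses` pulses, each a random-phase multisine with flat
#' amplitude spectrum over the excited band `[f_min, f_max]`. The defaults
#' reproduce the protocol used throughout this package: 10 one-second pulses
#' of randomized frequencies spanning 1--2000 Hz, sampled at 5000 Hz.
#'
#' @param n_pulses Number of pulses in the train (default 10).
#' @param pulse_duration Duration of one pulse in seconds (default 1).
#' @param f_min,f_max Lower/upper edge of the excited band in Hz
#'   (defaults 1 and 2000).
#' @param sample_rate Sampling rate in Hz (default 5000). Must exceed
#'   `2 * f_max` (Nyquist).
#' @param force_rms Target per-pulse RMS of the force signal in newtons
#'   (default 1).
#' @param preload Static compressive contact force in newtons (default 5).
#'   Metadata only: a linear model has no use for a constant offset.
#' @param seed Optional integer seed for the random phases.
#'
#' @return An object of class `"excitation_config"` (a validated list).
#' @examples
#' cfg <- excitation_config()
#' cfg$n_pulses
#' @export
excitation_config <- function(n_pulses = 10, pulse_duration = 1,
                              f_min = 1, f_max = 2000,
                              sample_rate = 5000, force_rms = 1,
                              preload = 5, seed = NULL) {
  if (!is.numeric(n_pulses) || length(n_pulses) != 1L || n_pulses < 1 ||
      n_pulses != round(n_pulses))
    stop("configuration error: `n_pulses` must be a positive integer")
  if (!is.numeric(pulse_duration) || pulse_duration <= 0)
    stop("configuration error: `pulse_duration` must be > 0")
  if (!is.numeric(f_min) || !is.numeric(f_max) || f_min <= 0 || f_min >= f_max)
    stop("configuration error: band must satisfy 0 < f_min < f_max")
  if (!is.numeric(sample_rate) || sample_rate <= 2 * f_max)
    stop("configuration error: sample_rate must exceed 2 * f_max (Nyquist)")
  n_samp <- pulse_duration * sample_rate
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("configuration error: pulse_duration * sample_rate must be an integer sample count")
  if (!is.numeric(force_rms) || force_rms <= 0)
    stop("configuration error: `force_rms` must be > 0")
  structure(list(
    n_pulses = as.integer(n_pulses), pulse_duration = pulse_duration,
    f_min = f_min, f_max = f_max, sample_rate = sample_rate,
    force_rms = force_rms, preload = preload,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "excitation_config")
}

#' @export
print.excitation_config <- function(x, ...) {
  cat(sprintf(
    "<excitation_config> %d x %.3g s pulses, band %g-%g Hz, fs %g Hz, RMS %g N\n",
    x$n_pulses, x$pulse_duration, x$f_min, x$f_max, x$sample_rate, x$force_rms))
  invisible(x)
}

# DFT bin indices (k in x[t] ~ exp(2*pi*i*k*t/N)) excited by the band, for one
# pulse of n samples at rate fs. Bin k corresponds to k/T Hz, T = n/fs.
excited_bins <- function(n, fs, f_min, f_max) {
  df <- fs / n
  k_lo <- ceiling(f_min / df - 1e-9)
  k_hi <- floor(f_max / df + 1e-9)
  k_hi <- min(k_hi, floor((n - 1) / 2)) # strictly below Nyquist
  if (k_lo > k_hi)
    stop("configuration error: excited band contains no DFT bins")
  k_lo:k_hi
}

#' Generate a pulse-train excitation signal
#'
#' Builds the force time series applied at T12: `n_pulses` concatenated
#' pulses, each an independent random-phase multisine. Within one pulse every
#' DFT-grid frequency inside `[f_min, f_max]` carries the same spectral
#' magnitude with a phase drawn uniformly on `[0, 2*pi)`; all out-of-band
#' bins are zero. Each pulse is rescaled in the time domain so its RMS equals
#' `force_rms`, which leaves the in-band spectrum flat. Holding the
#' per-frequency amplitude constant is what licenses treating the (weakly
#' nonlinear) in-vivo system as a linear equivalent.
#'
#' @param cfg An [excitation_config()].
#' @param seed Integer seed for the phase generator; overrides `cfg$seed`.
#'   The same seed reproduces the signal bit-for-bit.
#'
#' @return Numeric vector of force samples (N), length
#'   `n_pulses * pulse_duration * sample_rate`, with attributes
#'   `sample_rate` and `pulse_boundaries` (start index of each pulse).
#' @examples
#' force <- generate_excitation(excitation_config(), seed = 1)
#' length(force) # 50000
#' @export
generate_excitation <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "excitation_config"))
  seed <- if (!is.null(seed)) as.integer(seed) else cfg$seed
  n <- as.integer(round(cfg$pulse_duration * cfg$sample_rate))
  bins <- excited_bins(n, cfg$sample_rate, cfg$f_min, cfg$f_max)
  rng <- local_rng(seed)
  pulses <- lapply(seq_len(cfg$n_pulses), function(p) {
    phases <- rng(function() stats::runif(length(bins), 0, 2 * pi))
    spec <- complex(length.out = n)
    spec[bins + 1L] <- exp(1i * phases)
    spec[n - bins + 1L] <- Conj(spec[bins + 1L])
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    x * (cfg$force_rms / sqrt(mean(x^2)))
  })
  force <- unlist(pulses, use.names = FALSE)
  attr(force, "sample_rate") <- cfg$sample_rate
  attr(force, "pulse_boundaries") <- seq(1L, by = n, length.out = cfg$n_pulses)
  force
}

# Run `fn` under a temporary RNG state seeded with `seed` (NULL = use current
# stream). Returns a closure so several draws can share one seeded stream.
local_rng <- function(seed) {
  if (is.null(seed)) return(function(fn) fn())
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  state <- get(".Random.seed", envir = globalenv())
  if (has_old) assign(".Random.seed", old, envir = globalenv())
  function(fn) {
    has_cur <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    cur <- if (has_cur) get(".Random.seed", envir = globalenv())
    assign(".Random.seed", state, envir = globalenv())
    out <- fn()
    state <<- get(".Random.seed", envir = globalenv())
    if (has_cur) assign(".Random.seed", cur, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    out
  }
}

# Deterministically derive `n` independent sub-seeds (< 2^31) from one master
# seed without disturbing the caller's RNG stream.
derive_seeds <- function(seed, n) {
  rng <- local_rng(seed)
  rng(function() sample.int(.Machine$integer.max - 1L, n))
}
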