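#' Estimate pulse-averaged spectra of a recording
#'
#' Treats each pulse of the train as one estimation segment (no overlap) and
#' averages the per-segment auto-spectra of the force and of each
#' acceleration channel, and the complex cross-spectra of each acceleration
#' channel against the force, across pulses. The frequency grid is the DFT
#' grid of one pulse (1 Hz resolution for the default 1 s pulse), restricted
#' to the requested band. A rectangular window is the default: the multisine
#' excitation is periodic within its segment, so there is no leakage to
#' taper away; a Hann window is available for non-ideal inputs.
#'
#' Spectra are one-sided densities (`2 |X|^2 / (fs * n)`); the scaling
#' cancels in the FRF and coherence ratios but keeps AUC in interpretable
#' units.
#'
#' @param rec A [pulse_train_recording()].
#' @param band Numeric length-2, analysis band in Hz; must lie inside
#'   `(0, fs/2)`. Default `c(1, 2000)`.
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return Object of class `"spectral_set"`: list with `frequencies`,
#'   matrices `input_power` (replicated per sensor for convenience),
#'   `output_power`, `cross_power` (complex, acceleration x conjugate force),
#'   `n_averages`, `sensors`, and empty slots `frf`, `coherence`. If the
#'   recording holds a single pulse the spectra are still returned with
#'   `coherence_defined = FALSE`.
#' @seealso [compute_frf()], [compute_coherence()], [smooth_frf()]
#' @export
compute_spectra <- function(rec, band = c(1, 2000), window = c("rectangular", "hann")) {
  stopifnot(inherits(rec, "pulse_train_recording"))
  window <- match.arg(window)
  fs <- rec$sample_rate
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] > fs / 2)
    stop("configuration error: band must lie inside (0, Nyquist = ", fs / 2, " Hz)")
  n_pulse <- pulse_length_of(rec)
  n_avg <- n_pulses_of(rec)
  bins <- excited_bins(n_pulse, fs, band[1], band[2])
  freqs <- bins * fs / n_pulse
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(n_pulse) / n_pulse)
  } else rep(1, n_pulse)
  wnorm <- sum(w^2)
  sensors <- colnames(rec$accel)
  n_sens <- length(sensors)
  sxx <- numeric(length(bins))
  syy <- matrix(0, length(bins), n_sens, dimnames = list(NULL, sensors))
  sxy <- matrix(0i, length(bins), n_sens, dimnames = list(NULL, sensors))
  scale <- 2 / (fs * wnorm) # one-sided density, window-power normalized
  for (p in seq_len(n_avg)) {
    idx <- rec$pulse_boundaries[p]:(rec$pulse_boundaries[p] + n_pulse - 1L)
    Fw <- stats::fft(rec$force[idx] * w)[bins + 1L]
    sxx <- sxx + scale * Mod(Fw)^2
    for (s in seq_len(n_sens)) {
      Aw <- stats::fft(rec$accel[idx, s] * w)[bins + 1L]
      syy[, s] <- syy[, s] + scale * Mod(Aw)^2
      sxy[, s] <- sxy[, s] + scale * Aw * Conj(Fw)
    }
  }
  structure(list(
    frequencies = freqs,
    input_power = sxx / n_avg,
    output_power = syy / n_avg,
    cross_power = sxy / n_avg,
    n_averages = n_avg,
    coherence_defined = n_avg >= 2L,
    sensors = sensors,
    band = band,
    subject_id = rec$subject_id,
    trial_index = rec$trial_index,
    frf = NULL, frf_convention = NULL, coherence = NULL,
    mean_coherence = NULL, kernel_bins = NULL
  ), class = "spectral_set")
}

#' @export
print.spectral_set <- function(x, ...) {
  cat(sprintf("<spectral_set> %s trial %d: %d bins in [%g, %g] Hz, %d averages\n",
              x$subject_id, x$trial_index, length(x$frequencies),
              min(x$frequencies), max(x$frequencies), x$n_averages))
  if (!is.null(x$mean_coherence))
    cat("  mean coherence:",
        paste(sprintf("%s=%.2f", names(x$mean_coherence), x$mean_coherence),
              collapse = " "), "\n")
  invisible(x)
}

#' Compute the frequency response function
#'
#' Fills the FRF slot of a spectral set as the per-frequency ratio of output
#' power to input power at each sensor. Under the default `"power"`
#' convention this is `Syy / Sxx` (an `|H|^2`-like quantity); the
#' `"magnitude"` convention takes its square root. The peak-frequency outcome
#' is invariant to this (monotone) choice; AUC and RMS are not.
#'
#' @param spec A `"spectral_set"` from [compute_spectra()].
#' @param convention `"power"` (default) or `"magnitude"`.
#' @return The spectral set with `frf` (matrix, bins x sensors) and
#'   `frf_convention` filled.
#' @export
compute_frf <- function(spec, convention = c("power", "magnitude")) {
  stopifnot(inherits(spec, "spectral_set"))
  convention <- match.arg(convention)
  bad <- which(spec$input_power <= max(spec$input_power) * 1e-20)
  if (length(bad))
    stop("estimation error: zero input power at in-band bin(s) ",
         paste(utils::head(spec$frequencies[bad], 3), collapse = ", "), " Hz")
  frf <- spec$output_power / spec$input_power
  if (convention == "magnitude") frf <- sqrt(frf)
  spec$frf <- frf
  spec$frf_convention <- convention
  spec
}

#' Compute magnitude-squared coherence
#'
#' Fills the coherence slot: the squared modulus of the pulse-averaged
#' cross-spectrum divided by the product of the pulse-averaged input and
#' output auto-spectra, per frequency and sensor. Also records the per-sensor
#' mean coherence across the in-band grid, the quantity used for sensor
#' quality control. Coherence from a single segment is identically 1 and
#' carries no information, so at least 2 averages are required.
#'
#' @param spec A `"spectral_set"`.
#' @return The spectral set with `coherence` (bins x sensors, clamped to
#'   `[0, 1]`) and `mean_coherence` (named per-sensor vector) filled.
#' @export
compute_coherence <- function(spec) {
  stopifnot(inherits(spec, "spectral_set"))
  if (!spec$coherence_defined || spec$n_averages < 2L)
    stop("coherence-undefined error: need >= 2 pulse averages (single-segment coherence is identically 1)")
  coh <- Mod(spec$cross_power)^2 / (spec$input_power * spec$output_power)
  if (any(coh > 1 + 1e-9) || any(coh < -1e-9))
    stop("estimation error: coherence outside [0,1] beyond numerical slack")
  coh <- pmin(pmax(coh, 0), 1)
  dimnames(coh) <- dimnames(spec$output_power)
  spec$coherence <- coh
  spec$mean_coherence <- colMeans(coh)
  spec
}

#' Running-median smoothing
#'
#' Median filter with a symmetric window of `kernel_bins` samples; at the
#' edges the window shrinks symmetrically so the output at position `i` is
#' the median of the largest centered window that fits (endpoints are
#' therefore returned unchanged). Order statistics are used rather than a
#' linear kernel so isolated spectral spikes are removed without biasing the
#' level of smooth regions, and monotone runs are preserved.
#'
#' @param x Numeric vector.
#' @param kernel_bins Odd positive window length, at most `length(x)`.
#' @return Numeric vector, same length as `x`.
#' @export
running_median <- function(x, kernel_bins) {
  n <- length(x)
  if (!is.numeric(kernel_bins) || length(kernel_bins) != 1L ||
      kernel_bins < 1 || kernel_bins %% 2 != 1)
    stop("configuration error: kernel_bins must be odd and positive")
  if (kernel_bins > n)
    stop("configuration error: kernel_bins exceeds the grid length")
  if (kernel_bins == 1L || n <= 2L) return(x)
  half <- (kernel_bins - 1L) / 2L
  # interior: C-level running median; edges: symmetric shrinking windows
  out <- as.numeric(stats::runmed(x, kernel_bins, endrule = "keep"))
  edge <- unique(c(seq_len(min(half, n)), seq(max(n - half + 1L, 1L), n)))
  for (i in edge) {
    h <- min(half, i - 1L, n - i)
    out[i] <- stats::median(x[(i - h):(i + h)])
  }
  out
}

#' Smooth the FRF with a median filter
#'
#' Applies [running_median()] to each sensor's FRF. `kernel_bins = 1` is the
#' identity. The unsmoothed FRF is kept in `frf_raw`.
#'
#' @param spec A `"spectral_set"` with `frf` filled.
#' @param kernel_bins Odd window length in frequency bins (default 5).
#' @return The spectral set with `frf` replaced by its running median and
#'   `kernel_bins` recorded.
#' @export
smooth_frf <- function(spec, kernel_bins = 5) {
  stopifnot(inherits(spec, "spectral_set"))
  if (is.null(spec$frf))
    stop("estimation error: compute_frf() before smoothing")
  spec$frf_raw <- spec$frf
  spec$frf <- apply(spec$frf, 2L, running_median, kernel_bins = kernel_bins)
  dimnames(spec$frf) <- dimnames(spec$frf_raw)
  spec$kernel_bins <- kernel_bins
  spec
}

#' Full spectral analysis of one recording
#'
#' Convenience wrapper: [compute_spectra()], [compute_frf()],
#' [compute_coherence()], [smooth_frf()] in sequence.
#'
#' @inheritParams compute_spectra
#' @inheritParams compute_frf
#' @param kernel_bins Median-filter window (default 5); see [smooth_frf()].
#' @return A complete `"spectral_set"`.
#' @export
analyze_recording <- function(rec, band = c(1, 2000), kernel_bins = 5,
                              convention = c("power", "magnitude"),
                              window = c("rectangular", "hann")) {
  spec <- compute_spectra(rec, band = band, window = window)
  spec <- compute_frf(spec, convention = convention)
  spec <- compute_coherence(spec)
  smooth_frf(spec, kernel_bins = kernel_bins)
}
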