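#' Frequency at peak FRF amplitude (PEAK)
#'
#' Frequency of the global maximum of the (smoothed) FRF over the in-band
#' grid. Ties are broken toward the lowest frequency. PEAK is invariant
#' under any strictly increasing transform of the FRF, so it does not depend
#' on whether the power or magnitude convention is used.
#'
#' @param frf Numeric vector, FRF values on the grid.
#' @param frequencies Numeric vector of grid frequencies (Hz), same length.
#' @return Peak frequency in Hz.
#' @examples
#' peak_frequency(c(1, 3, 2), c(10, 20, 30)) # 20
#' @export
peak_frequency <- function(frf, frequencies) {
  if (length(frf) == 0L || length(frf) != length(frequencies))
    stop("validation error: frf and frequency grid must be non-empty and matched")
  frequencies[which.max(frf)] # which.max returns the first (lowest-f) maximum
}

#' Area under the FRF curve (AUC)
#'
#' Trapezoidal integral of the FRF over the in-band frequency grid.
#'
#' @inheritParams peak_frequency
#' @return AUC in FRF-units x Hz.
#' @examples
#' area_under_curve(c(0, 2), c(0, 1)) # 1
#' @export
area_under_curve <- function(frf, frequencies) {
  if (length(frf) != length(frequencies))
    stop("validation error: frf and frequency grid must be matched")
  if (length(frf) < 2L)
    stop("validation error: AUC needs at least a two-point grid")
  if (any(diff(frequencies) <= 0))
    stop("validation error: frequency grid must be strictly increasing")
  sum(diff(frequencies) * (utils::head(frf, -1) + utils::tail(frf, -1)) / 2)
}

#' Root mean square of the FRF (RMS)
#'
#' Square root of the arithmetic mean of the squared FRF values across the
#' in-band bins (the grid is uniform, so no frequency weighting is applied).
#'
#' @inheritParams peak_frequency
#' @return RMS in FRF units.
#' @examples
#' root_mean_square(c(3, 4)) # sqrt(12.5)
#' @export
root_mean_square <- function(frf, frequencies = NULL) {
  if (length(frf) == 0L)
    stop("validation error: empty FRF")
  sqrt(mean(frf^2))
}

#' Coherence-based sensor quality control
#'
#' A sensor is retained only if its in-band mean coherence reaches the
#' threshold (inclusive). Low coherence indicates that soft-tissue
#' attenuation has driven the signal-to-noise ratio too low for the FRF to
#' be meaningful, as happens at the sensor most distant from the vibration
#' source.
#'
#' @param mean_coherence Named numeric vector of per-sensor mean coherence
#'   values in `[0, 1]`.
#' @param threshold Inclusion threshold in `(0, 1)`; default 0.5.
#' @return Named logical vector: `TRUE` = included.
#' @examples
#' qc_sensors(c(L1 = 0.71, L2 = 0.82, L3 = 0.83, L4 = 0.82, L5 = 0.15))
#' @export
qc_sensors <- function(mean_coherence, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("validation error: qc threshold must lie in (0, 1)")
  mean_coherence >= threshold
}

#' Per-sensor outcomes of one analyzed trial
#'
#' Reduces each sensor's smoothed FRF to PEAK, AUC and RMS, attaching the
#' sensor's mean coherence and QC inclusion flag.
#'
#' @param spec A complete `"spectral_set"` (see [analyze_recording()]).
#' @param qc_threshold Coherence inclusion threshold (default 0.5).
#' @return data.frame with one row per sensor: `sensor`, `peak_hz`, `auc`,
#'   `rms`, `mean_coherence`, `included`.
#' @export
sensor_outcomes <- function(spec, qc_threshold = 0.5) {
  stopifnot(inherits(spec, "spectral_set"))
  if (is.null(spec$frf))
    stop("estimation error: compute_frf() before extracting outcomes")
  if (is.null(spec$mean_coherence))
    stop("estimation error: compute_coherence() before extracting outcomes")
  inc <- qc_sensors(spec$mean_coherence, qc_threshold)
  data.frame(
    sensor = spec$sensors,
    peak_hz = apply(spec$frf, 2L, peak_frequency, frequencies = spec$frequencies),
    auc = apply(spec$frf, 2L, area_under_curve, frequencies = spec$frequencies),
    rms = apply(spec$frf, 2L, root_mean_square),
    mean_coherence = as.numeric(spec$mean_coherence),
    included = as.logical(inc),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate a subject's trials
#'
#' Computes per-trial sensor outcomes and averages them across trials per
#' sensor. A sensor failing coherence QC in any trial is excluded from the
#' subject overall (a deliberately strict rule: it guarantees the same
#' sensor set underlies every trial mean).
#'
#' @param specs List of complete `"spectral_set"` objects, one per trial
#'   (three under the default protocol), with identical frequency grids.
#' @param qc_threshold Coherence inclusion threshold (default 0.5).
#' @return Object of class `"subject_outcomes"`: list with `subject_id`,
#'   `trials` (long data.frame: trial, sensor, peak_hz, auc, rms,
#'   mean_coherence, included) and `means` (per-sensor trial means with the
#'   overall `included` flag).
#' @export
summarize_subject <- function(specs, qc_threshold = 0.5) {
  if (!length(specs)) stop("validation error: no trials supplied")
  if (inherits(specs, "spectral_set")) specs <- list(specs)
  grids <- lapply(specs, `[[`, "frequencies")
  if (length(unique(vapply(grids, length, integer(1)))) != 1L ||
      any(vapply(grids[-1], function(g) any(g != grids[[1]]), logical(1))))
    stop("validation error: trials have mismatched frequency grids")
  per_trial <- do.call(rbind, lapply(seq_along(specs), function(i) {
    cbind(trial = specs[[i]]$trial_index %||% i,
          sensor_outcomes(specs[[i]], qc_threshold))
  }))
  included_overall <- tapply(per_trial$included, per_trial$sensor, all)
  means <- do.call(rbind, lapply(split(per_trial, per_trial$sensor), function(d) {
    data.frame(sensor = d$sensor[1],
               peak_hz = mean(d$peak_hz), auc = mean(d$auc), rms = mean(d$rms),
               mean_coherence = mean(d$mean_coherence),
               included = all(d$included),
               stringsAsFactors = FALSE)
  }))
  means <- means[match(specs[[1]]$sensors, means$sensor), ]
  row.names(means) <- NULL
  structure(list(subject_id = specs[[1]]$subject_id,
                 trials = per_trial, means = means),
            class = "subject_outcomes")
}

#' @export
print.subject_outcomes <- function(x, ...) {
  cat(sprintf("<subject_outcomes> %s (%d trials)\n", x$subject_id,
              length(unique(x$trials$trial))))
  print(x$means, digits = 4)
  invisible(x)
}

#' Analyze all trials of one subject
#'
#' Runs [analyze_recording()] on each trial recording of a subject and
#' aggregates with [summarize_subject()].
#'
#' @param recordings List of [pulse_train_recording()] for one subject.
#' @inheritParams analyze_recording
#' @inheritParams summarize_subject
#' @return A `"subject_outcomes"`.
#' @export
analyze_subject <- function(recordings, band = c(1, 2000), kernel_bins = 5,
                            convention = "power", qc_threshold = 0.5) {
  specs <- lapply(recordings, analyze_recording, band = band,
                  kernel_bins = kernel_bins, convention = convention)
  summarize_subject(specs, qc_threshold = qc_threshold)
}
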