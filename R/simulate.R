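#' Pulse-train recording container
#'
#' One subject-trial of the SHM protocol: the force channel measured at T12
#' and one acceleration channel per lumbar sensor, all sampled at the same
#' rate and segmented into equal pulses.
#'
#' @param force Numeric vector, force at T12 (N).
#' @param accel Numeric matrix (samples x sensors) of accelerations (m/s^2),
#'   with sensor labels as column names.
#' @param sample_rate Sampling rate (Hz).
#' @param pulse_boundaries Integer vector of start indices of each pulse;
#'   must partition the record into equal, non-overlapping segments.
#' @param subject_id,trial_index Identifiers (trial_index in 1..3 under the
#'   default protocol).
#' @return Object of class `"pulse_train_recording"`.
#' @export
pulse_train_recording <- function(force, accel, sample_rate,
                                  pulse_boundaries,
                                  subject_id = "S1", trial_index = 1L) {
  accel <- as.matrix(accel)
  n <- length(force)
  if (nrow(accel) != n)
    stop("validation error: force and acceleration channels differ in length")
  if (is.null(colnames(accel)))
    stop("validation error: acceleration channels must be labeled")
  pb <- as.integer(pulse_boundaries)
  if (length(pb) < 1L || pb[1] != 1L)
    stop("validation error: pulse_boundaries must start at sample 1")
  seg <- if (length(pb) > 1L) diff(pb) else n
  if (length(unique(c(seg, n - pb[length(pb)] + 1L))) != 1L)
    stop("validation error: pulse_boundaries must partition the record into equal pulses")
  structure(list(
    subject_id = subject_id, trial_index = as.integer(trial_index),
    sample_rate = sample_rate, force = as.numeric(force), accel = accel,
    pulse_boundaries = pb
  ), class = "pulse_train_recording")
}

#' @export
print.pulse_train_recording <- function(x, ...) {
  cat(sprintf(
    "<pulse_train_recording> %s trial %d: %d pulses x %d samples at %g Hz, sensors %s\n",
    x$subject_id, x$trial_index, length(x$pulse_boundaries),
    diff(x$pulse_boundaries[1:2]), x$sample_rate,
    paste(colnames(x$accel), collapse = ", ")))
  invisible(x)
}

n_pulses_of <- function(rec) length(rec$pulse_boundaries)

pulse_length_of <- function(rec) {
  if (length(rec$pulse_boundaries) > 1L) diff(rec$pulse_boundaries[1:2])
  else length(rec$force)
}

#' Simulate a sensor recording from a chain model
#'
#' Drives the linear time-invariant chain at its first node with the supplied
#' force pulse train and synthesizes the acceleration at every sensor node.
#' Because each pulse is periodic within its segment, the response is
#' computed pulse-by-pulse in the frequency domain (multiplication by the
#' chain's acceleration FRF on the pulse DFT grid), which is exact for the
#' multisine excitation; the result is scaled by each sensor's soft-tissue
#' attenuation gain and corrupted with additive white Gaussian noise of RMS
#' `model$noise_rms`.
#'
#' @param model A [spine_model()].
#' @param force Force signal from [generate_excitation()] (carries
#'   `sample_rate` and `pulse_boundaries` attributes), or any numeric vector
#'   if `sample_rate`/`pulse_boundaries` are given explicitly.
#' @param sample_rate,pulse_boundaries Override/supply the signal metadata.
#' @param subject_id,trial_index Identifiers stored in the recording.
#' @param noise_seed Integer seed for the measurement noise; the simulation
#'   is deterministic given the force signal and this seed.
#' @param frf Optional precomputed [chain_frf()] matrix for the pulse DFT
#'   grid (internal use: avoids recomputation across trials of one subject).
#' @return A [pulse_train_recording()].
#' @examples
#' cfg <- excitation_config(n_pulses = 2)
#' force <- generate_excitation(cfg, seed = 1)
#' rec <- simulate_recording(spine_model(), force, noise_seed = 2)
#' @export
simulate_recording <- function(model, force, sample_rate = NULL,
                               pulse_boundaries = NULL,
                               subject_id = "S1", trial_index = 1L,
                               noise_seed = NULL, frf = NULL) {
  stopifnot(inherits(model, "spine_model"))
  fs <- sample_rate %||% attr(force, "sample_rate")
  pb <- pulse_boundaries %||% attr(force, "pulse_boundaries")
  if (is.null(fs))
    stop("configuration error: sampling rate of the force signal is unknown")
  if (is.null(pb)) pb <- 1L
  n_tot <- length(force)
  n_pulse <- if (length(pb) > 1L) diff(pb[1:2]) else n_tot
  if (n_tot != n_pulse * length(pb))
    stop("configuration error: force length does not match pulse segmentation")
  half <- floor(n_pulse / 2)
  if (is.null(frf)) {
    freqs <- (1:half) * fs / n_pulse
    frf <- chain_frf(model, freqs)
  } else if (nrow(frf) != half) {
    stop("configuration error: sampling-rate mismatch between force and precomputed FRF")
  }
  n_sens <- ncol(frf)
  accel <- matrix(0, n_tot, n_sens,
                  dimnames = list(NULL, colnames(frf)))
  even <- n_pulse %% 2L == 0L
  for (p in seq_along(pb)) {
    idx <- pb[p]:(pb[p] + n_pulse - 1L)
    Fw <- stats::fft(force[idx])
    for (s in seq_len(n_sens)) {
      spec <- complex(length.out = n_pulse)
      h <- frf[, s]
      if (even) h[half] <- Re(h[half]) # Nyquist bin must stay real
      spec[2:(half + 1L)] <- Fw[2:(half + 1L)] * h
      lo <- if (even) half - 1L else half
      if (lo >= 1L)
        spec[n_pulse:(n_pulse - lo + 1L)] <- Conj(spec[2:(lo + 1L)])
      accel[idx, s] <- Re(stats::fft(spec, inverse = TRUE)) / n_pulse
    }
  }
  if (model$noise_rms > 0) {
    rng <- local_rng(noise_seed)
    noise <- rng(function() stats::rnorm(n_tot * n_sens, sd = model$noise_rms))
    accel <- accel + matrix(noise, n_tot, n_sens)
  }
  pulse_train_recording(force = as.numeric(force), accel = accel,
                        sample_rate = fs, pulse_boundaries = pb,
                        subject_id = subject_id, trial_index = trial_index)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Multiply a model's physical parameters by i.i.d. lognormal factors with
# unit mean and coefficient of variation `cv` (cv = 0 returns the model
# unchanged). Attenuation and noise are measurement-chain properties and are
# not perturbed.
perturb_model <- function(model, cv, rng) {
  if (cv <= 0) return(model)
  sdlog <- sqrt(log(1 + cv^2))
  mulog <- -sdlog^2 / 2
  n_par <- length(model$masses) + 2 * length(model$stiffnesses) + 2L
  f <- rng(function() stats::rlnorm(n_par, mulog, sdlog))
  out <- model
  i <- 0L
  nm <- length(model$masses); nk <- length(model$stiffnesses)
  out$masses <- model$masses * f[i + seq_len(nm)]; i <- i + nm
  out$stiffnesses <- model$stiffnesses * f[i + seq_len(nk)]; i <- i + nk
  out$dampings <- model$dampings * f[i + seq_len(nk)]; i <- i + nk
  out$ground_stiffness <- model$ground_stiffness * f[i + 1L]
  out$ground_damping <- model$ground_damping * f[i + 2L]
  out
}

#' Generate a synthetic twin cohort
#'
#' Emulates the twin-control study design: monozygotic pairs whose spines are
#' structurally concordant, plus pairs in which exactly one twin carries a
#' localized structural alteration (discordant pairs). Each pair draws a
#' shared base model by perturbing the default chain with between-pair
#' variability; each twin then receives a small independent within-pair
#' perturbation. In discordant pairs the alteration is applied to the
#' second twin of the pair (the twin with the higher subject id), so the
#' signed within-pair difference (lower id minus higher) has a consistent
#' sign across pairs. Three pulse-train trials are recorded per subject with
#' independent excitation phases and measurement noise.
#'
#' @param n_pairs_concordant,n_pairs_discordant Number of pairs per group.
#' @param variability_within Coefficient of variation of the within-pair
#'   (twin vs twin) parameter perturbation; default 0.02.
#' @param variability_between CV of the between-pair perturbation of the
#'   default model; default 0.10.
#' @param alt [alteration()] applied to one twin of each discordant pair;
#'   default halves the stiffness of the link above L2 ("compression
#'   fracture").
#' @param cfg [excitation_config()]; default protocol.
#' @param n_trials Trials per subject (default 3).
#' @param base_model Base [spine_model()] (default [spine_model()]).
#' @param seed Master seed; every random draw (models, phases, noise,
#'   metadata) derives from it, so the cohort is fully reproducible.
#' @return List of class `"twin_cohort"` with elements
#'   `recordings` (list of [pulse_train_recording()]),
#'   `manifest` (data.frame: recording index, subject_id, pair_id, twin,
#'   trial, concordance, alteration label),
#'   `metadata` (one row per subject: subject_id, pair_id, sex, age, bmi,
#'   concordance columns — synthetic anthropometrics for covariate use), and
#'   `ground_truth` (data.frame per pair: pair_id, concordance, altered
#'   subject and level).
#' @examples
#' coh <- generate_twin_cohort(1, 1, cfg = excitation_config(n_pulses = 2), seed = 1)
#' nrow(coh$manifest) # 2 pairs x 2 twins x 3 trials = 12
#' @export
generate_twin_cohort <- function(n_pairs_concordant, n_pairs_discordant,
                                 variability_within = 0.02,
                                 variability_between = 0.10,
                                 alt = alteration("L2", stiffness_factor = 0.5,
                                                  label = "compression fracture"),
                                 cfg = excitation_config(),
                                 n_trials = 3L,
                                 base_model = spine_model(),
                                 seed = NULL) {
  if (n_pairs_concordant < 0 || n_pairs_discordant < 0)
    stop("validation error: pair counts must be non-negative")
  if (variability_within < 0 || variability_between < 0)
    stop("validation error: variability must be non-negative")
  n_pairs <- n_pairs_concordant + n_pairs_discordant
  seeds <- derive_seeds(seed %||% stats::runif(1, 1, 2^30), 3L)
  rng_model <- local_rng(seeds[1])
  rng_phase <- local_rng(seeds[2])
  rng_noise <- local_rng(seeds[3])

  concordance <- rep(c("Concordant", "Discordant"),
                     c(n_pairs_concordant, n_pairs_discordant))
  recordings <- list(); manifest <- list(); metadata <- list(); truth <- list()
  n_pulse <- as.integer(round(cfg$pulse_duration * cfg$sample_rate))
  freqs <- (1:floor(n_pulse / 2)) * cfg$sample_rate / n_pulse
  ri <- 0L
  for (p in seq_len(n_pairs)) {
    pair_id <- sprintf("P%02d", p)
    pair_model <- perturb_model(base_model, variability_between, rng_model)
    disc <- concordance[p] == "Discordant"
    # synthetic anthropometrics: shared within a pair up to small differences
    sex <- rng_model(function() sample(c("F", "M"), 1))
    age <- rng_model(function() round(stats::runif(1, 40, 50)))
    bmi_pair <- rng_model(function() stats::rnorm(1, 25.5, 3))
    # both twins of a pair are excited with the same pulse trains (one
    # session per trial index), so identical twins yield identical
    # noiseless responses
    phase_seeds <- rng_phase(function()
      sample.int(.Machine$integer.max - 1L, n_trials))
    forces <- lapply(phase_seeds, function(s) generate_excitation(cfg, seed = s))
    for (tw in 1:2) {
      subject_id <- sprintf("%s-T%d", pair_id, tw)
      twin_model <- perturb_model(pair_model, variability_within, rng_model)
      altered <- disc && tw == 2L
      if (altered) twin_model <- apply_alteration(twin_model, alt)
      H <- chain_frf(twin_model, freqs)
      bmi <- bmi_pair + rng_model(function() stats::rnorm(1, 0, 0.8))
      metadata[[length(metadata) + 1L]] <- data.frame(
        subject_id = subject_id, pair_id = pair_id, sex = sex, age = age,
        bmi = round(bmi, 2),
        selfreport_concordance = concordance[p],
        mri_concordance = concordance[p],
        status_note = if (altered) alt$label else "Normal",
        stringsAsFactors = FALSE)
      for (tr in seq_len(n_trials)) {
        noise_seed <- rng_noise(function() sample.int(.Machine$integer.max - 1L, 1))
        rec <- simulate_recording(twin_model, forces[[tr]],
                                  subject_id = subject_id, trial_index = tr,
                                  noise_seed = noise_seed, frf = H)
        ri <- ri + 1L
        recordings[[ri]] <- rec
        manifest[[ri]] <- data.frame(
          recording = ri, subject_id = subject_id, pair_id = pair_id,
          twin = tw, trial = tr, concordance = concordance[p],
          alteration = if (altered) alt$label else "",
          stringsAsFactors = FALSE)
      }
    }
    truth[[p]] <- data.frame(
      pair_id = pair_id, concordance = concordance[p],
      altered_subject = if (disc) sprintf("%s-T2", pair_id) else NA_character_,
      altered_level = if (disc) alt$level else NA_character_,
      stringsAsFactors = FALSE)
  }
  structure(list(
    recordings = recordings,
    manifest = if (n_pairs) do.call(rbind, manifest) else
      data.frame(recording = integer(0), subject_id = character(0),
                 pair_id = character(0), twin = integer(0), trial = integer(0),
                 concordance = character(0), alteration = character(0)),
    metadata = if (n_pairs) do.call(rbind, metadata) else
      data.frame(subject_id = character(0), pair_id = character(0)),
    ground_truth = if (n_pairs) do.call(rbind, truth) else
      data.frame(pair_id = character(0), concordance = character(0)),
    cfg = cfg, seed = seed
  ), class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<twin_cohort> %d pairs (%d concordant, %d discordant), %d recordings\n",
              nrow(gt), sum(gt$concordance == "Concordant"),
              sum(gt$concordance == "Discordant"), length(x$recordings)))
  invisible(x)
}
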