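#' Write / read a pulse-train recording
#'
#' Recordings are stored as plain CSV: one sample per row, columns
#' `force_T12` then `accel_<sensor>` for each sensor, preceded by `#`-prefixed
#' header lines carrying `subject_id`, `trial_index`, `sample_rate`,
#' `n_pulses` and the config hash/seed provenance. The round trip is
#' lossless to full double precision (`%.17g`).
#'
#' @param rec A [pulse_train_recording()].
#' @param path Output file path.
#' @param provenance Optional named list (e.g. `config_hash`, `seed`) written
#'   into the header.
#' @return `write_recording()`: `path`, invisibly. `read_recording()`: a
#'   [pulse_train_recording()].
#' @export
write_recording <- function(rec, path, provenance = NULL) {
  stopifnot(inherits(rec, "pulse_train_recording"))
  hdr <- c(
    sprintf("# spinevib recording v1"),
    sprintf("# subject_id: %s", rec$subject_id),
    sprintf("# trial_index: %d", rec$trial_index),
    sprintf("# sample_rate: %.17g", rec$sample_rate),
    sprintf("# n_pulses: %d", n_pulses_of(rec)),
    vapply(names(provenance %||% list()), function(k)
      sprintf("# %s: %s", k, provenance[[k]]), character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  dat <- cbind(force_T12 = rec$force, rec$accel)
  colnames(dat) <- c("force_T12", paste0("accel_", colnames(rec$accel)))
  writeLines(paste(colnames(dat), collapse = ","), con)
  writeLines(do.call(sprintf, c(
    list(paste(rep("%.17g", ncol(dat)), collapse = ",")),
    lapply(seq_len(ncol(dat)), function(j) dat[, j]))), con)
  invisible(path)
}

#' @rdname write_recording
#' @param expected_sensors Sensor labels that must be present (default
#'   L1..L5); a file missing one raises a format error naming it.
#' @export
read_recording <- function(path, expected_sensors = c("L1", "L2", "L3", "L4", "L5")) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (!length(hdr) || !grepl("spinevib recording", lines[1]))
    stop("format error: ", path, " is not a spinevib recording (missing header)")
  meta <- list()
  for (l in lines[hdr][-1]) {
    m <- regmatches(l, regexec("^# ([^:]+): (.*)$", l))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  for (k in c("subject_id", "trial_index", "sample_rate", "n_pulses"))
    if (is.null(meta[[k]]))
      stop("format error: header field '", k, "' missing in ", path)
  body <- lines[-hdr]
  cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (cols[1] != "force_T12")
    stop("format error: first channel must be force_T12 (line ",
         length(hdr) + 1L, ")")
  sens <- sub("^accel_", "", cols[-1])
  miss <- setdiff(expected_sensors, sens)
  if (length(miss))
    stop("format error: missing acceleration channel(s): ",
         paste(miss, collapse = ", "))
  dat <- utils::read.csv(textConnection(body), header = TRUE)
  if (anyNA(dat))
    stop("format error: non-numeric or missing sample in ", path)
  n_pulses <- as.integer(meta$n_pulses)
  if (nrow(dat) %% n_pulses != 0L)
    stop("format error: channel length ", nrow(dat),
         " not divisible by n_pulses ", n_pulses)
  accel <- as.matrix(dat[, -1, drop = FALSE])
  colnames(accel) <- sens
  pulse_train_recording(
    force = dat[[1]], accel = accel,
    sample_rate = as.numeric(meta$sample_rate),
    pulse_boundaries = seq(1L, by = nrow(dat) %/% n_pulses,
                           length.out = n_pulses),
    subject_id = meta$subject_id,
    trial_index = as.integer(meta$trial_index))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline — excitation, model, spectral
#' estimation, QC and statistics — into one object that round-trips through
#' YAML, so a whole analysis is reproducible from a single plain-text file
#' plus a seed.
#'
#' @param excitation An [excitation_config()].
#' @param model A [spine_model()].
#' @param band Analysis band in Hz.
#' @param window Spectral window (`"rectangular"` or `"hann"`).
#' @param kernel_bins Median-filter window (odd).
#' @param convention FRF convention (`"power"` or `"magnitude"`).
#' @param qc_threshold Coherence inclusion threshold.
#' @param method Group test (`"paired-t"` or `"ancova"`).
#' @param n_pairs_concordant,n_pairs_discordant Cohort design.
#' @param variability_within,variability_between Twin/pair parameter CVs.
#' @param alteration_level,alteration_stiffness_factor,alteration_mass_factor,alteration_label
#'   Alteration applied to one twin of each discordant pair.
#' @param seed Master seed.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(excitation = excitation_config(),
                            model = spine_model(),
                            band = c(1, 2000), window = "rectangular",
                            kernel_bins = 5, convention = "power",
                            qc_threshold = 0.5, method = "paired-t",
                            n_pairs_concordant = 5, n_pairs_discordant = 5,
                            variability_within = 0.02,
                            variability_between = 0.10,
                            alteration_level = "L2",
                            alteration_stiffness_factor = 0.5,
                            alteration_mass_factor = 1,
                            alteration_label = "compression fracture",
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `"pipeline_config"`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$excitation <- unclass(x$excitation)
  x$model <- lapply(unclass(x$model), function(v)
    if (is.numeric(v)) as.numeric(v) else v)
  x$model$sensor_attenuation <- as.numeric(config$model$sensor_attenuation)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  exc <- do.call(excitation_config, x$excitation[
    setdiff(names(x$excitation), character(0))])
  mod <- spine_model(
    masses = as.numeric(x$model$masses),
    stiffnesses = as.numeric(x$model$stiffnesses),
    dampings = as.numeric(x$model$dampings),
    ground_stiffness = x$model$ground_stiffness,
    ground_damping = x$model$ground_damping,
    sensor_attenuation = as.numeric(x$model$sensor_attenuation),
    noise_rms = x$model$noise_rms,
    node_labels = as.character(x$model$node_labels))
  args <- x[setdiff(names(x), c("excitation", "model"))]
  args$band <- as.numeric(args$band)
  do.call(pipeline_config, c(list(excitation = exc, model = mod), args))
}

# FNV-1a 32-bit hash of a config's YAML serialization; embedded in artifact
# headers so outputs can be traced to the exact configuration.
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(unclass(config), digits.d = 15)),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256 # bytes are < 256, so the XOR only touches the low byte
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # h * 16777619 mod 2^32 in exact double arithmetic (split at 16 bits)
    hi <- h %/% 65536; lo2 <- h %% 65536
    h <- (lo2 * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

alteration_from_config <- function(config) {
  alteration(config$alteration_level,
             stiffness_factor = config$alteration_stiffness_factor,
             mass_factor = config$alteration_mass_factor,
             label = config$alteration_label)
}
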