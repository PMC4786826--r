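make_rec <- function(force, accel_list, fs = 5000, n_pulses = 1) {
  n <- length(force)
  pulse_train_recording(force, do.call(cbind, accel_list), fs,
                        seq(1L, by = n / n_pulses, length.out = n_pulses))
}

test_that("identity channels give equal input and output power at every bin", {
  set.seed(2)
  force <- generate_excitation(short_cfg(2), seed = 2)
  rec <- make_rec(as.numeric(force), list(L1 = as.numeric(force)), n_pulses = 2)
  spec <- compute_spectra(rec, band = short_band)
  expect_equal(spec$output_power[, "L1"], spec$input_power, tolerance = 1e-10)
  expect_equal(spec$n_averages, 2L)
  frf <- compute_frf(spec)$frf
  expect_equal(unname(frf[, "L1"]), rep(1, nrow(frf)), tolerance = 1e-10)
})

test_that("a pure tone concentrates its spectral mass in its own bin (DFT oracle)", {
  fs <- 1000; n <- 200 # 5 Hz grid
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 50 * t)
  y <- 0.5 * sin(2 * pi * 50 * t + 0.3)
  rec <- make_rec(x, list(L1 = y), fs = fs)
  spec <- compute_spectra(rec, band = c(5, 400))
  i50 <- which(spec$frequencies == 50)
  expect_gt(spec$input_power[i50], 1e6 * max(spec$input_power[-i50]))
  # bin-by-bin agreement with a direct DFT periodogram
  bins <- round(spec$frequencies * n / fs)
  X <- oracle_dft(x, bins)
  expect_equal(spec$input_power, 2 * Mod(X)^2 / (fs * n), tolerance = 1e-10)
  Y <- oracle_dft(y, bins)
  expect_equal(unname(spec$cross_power[, "L1"]), 2 * Y * Conj(X) / (fs * n),
               tolerance = 1e-10)
})

test_that("band and input-power preconditions are enforced", {
  force <- generate_excitation(short_cfg(2), seed = 3)
  rec <- make_rec(as.numeric(force), list(L1 = rnorm(5000)), n_pulses = 2)
  expect_error(compute_spectra(rec, band = c(1, 3000)), "Nyquist")
  expect_error(compute_spectra(rec, band = c(-5, 100)), "band")
  # force has no power below f_min of the generator: FRF must refuse
  spec <- compute_spectra(rec, band = c(2, 2200))
  expect_error(compute_frf(spec), "zero input power")
})

test_that("default protocol averages 10 pulses", {
  force <- generate_excitation(excitation_config(), seed = 4)
  rec <- simulate_recording(test_chain(), force)
  spec <- compute_spectra(rec)
  expect_equal(spec$n_averages, 10L)
})

test_that("single-pulse recordings return spectra but refuse coherence", {
  force <- generate_excitation(excitation_config(n_pulses = 1), seed = 5)
  rec <- simulate_recording(test_chain(), force)
  spec <- compute_spectra(rec)
  expect_false(spec$coherence_defined)
  expect_s3_class(spec, "spectral_set")
  expect_error(compute_coherence(spec), "coherence-undefined")
})

test_that("noiseless linear responses are coherent; independent noise is not", {
  cfg <- short_cfg()
  force <- generate_excitation(cfg, seed = 6)
  rec <- simulate_recording(test_chain(), force)
  spec <- compute_coherence(compute_spectra(rec, band = short_band))
  expect_gt(min(spec$coherence), 0.99)

  # pure-noise output, 10 averages: mean coherence ~ 1/n_averages
  cfg10 <- excitation_config()
  mean_cohs <- vapply(1:20, function(s) {
    f <- generate_excitation(cfg10, seed = s)
    set.seed(1000 + s)
    rec <- make_rec(as.numeric(f), list(L1 = rnorm(length(f))), n_pulses = 10)
    compute_coherence(compute_spectra(rec))$mean_coherence[["L1"]]
  }, numeric(1))
  expect_lt(mean(mean_cohs), 0.3)
  expect_equal(mean(mean_cohs), 1 / 10, tolerance = 0.15)
})

test_that("coherence is bounded in [0,1] on arbitrary random fixtures", {
  set.seed(42)
  for (i in 1:10) {
    n <- 400
    x <- rnorm(n)
    y <- stats::filter(x, rep(0.3, 3), sides = 1)
    y[is.na(y)] <- 0
    rec <- make_rec(x, list(L1 = as.numeric(y) + rnorm(n, sd = runif(1, 0, 2))),
                    fs = 1000, n_pulses = 4)
    coh <- compute_coherence(compute_spectra(rec, band = c(10, 490)))$coherence
    expect_true(all(coh >= 0 & coh <= 1))
  }
})

test_that("adding output noise strictly lowers mean coherence (paired seeds)", {
  cfg <- short_cfg()
  force <- generate_excitation(cfg, seed = 9)
  clean <- simulate_recording(test_chain(), force)
  for (s in 1:3) {
    noisy <- clean
    set.seed(s)
    noisy$accel <- noisy$accel + matrix(rnorm(length(noisy$accel), sd = 0.3),
                                        nrow(noisy$accel))
    mc_clean <- compute_coherence(compute_spectra(clean, short_band))$mean_coherence
    mc_noisy <- compute_coherence(compute_spectra(noisy, short_band))$mean_coherence
    expect_true(all(mc_noisy < mc_clean))
  }
})

test_that("averaging identical pulses equals the single-pulse periodogram", {
  f1 <- generate_excitation(excitation_config(n_pulses = 1, pulse_duration = 0.5),
                            seed = 11)
  m <- test_chain()
  r1 <- simulate_recording(m, f1)
  rep3 <- rep(as.numeric(f1), 3)
  r3 <- simulate_recording(m, rep3, sample_rate = 5000,
                           pulse_boundaries = c(1L, 2501L, 5001L))
  s1 <- compute_spectra(r1, short_band)
  s3 <- compute_spectra(r3, short_band)
  expect_equal(s1$input_power, s3$input_power, tolerance = 1e-9)
  expect_equal(s1$output_power, s3$output_power, tolerance = 1e-9)
})

test_that("FRF conventions scale as |H| and |H|^2 and pipeline is deterministic", {
  force <- generate_excitation(short_cfg(2), seed = 12)
  rec <- make_rec(as.numeric(force), list(L1 = 2 * as.numeric(force)),
                  n_pulses = 2)
  spec <- compute_spectra(rec, short_band)
  expect_equal(unname(compute_frf(spec, "power")$frf[, 1]),
               rep(4, length(spec$frequencies)), tolerance = 1e-10)
  expect_equal(unname(compute_frf(spec, "magnitude")$frf[, 1]),
               rep(2, length(spec$frequencies)), tolerance = 1e-10)

  rec2 <- simulate_recording(spine_model(),
                             generate_excitation(short_cfg(2), seed = 13),
                             noise_seed = 1)
  a <- analyze_recording(rec2, band = short_band)
  b <- analyze_recording(rec2, band = short_band)
  expect_identical(a, b)
})
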