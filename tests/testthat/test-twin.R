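# build a subject_outcomes object directly from chosen per-sensor means
fake_outcomes <- function(subject_id, peak, auc = peak * 10, rms = peak / 10,
                          sensors = c("L1", "L2"), included = TRUE) {
  means <- data.frame(sensor = sensors, peak_hz = peak, auc = auc, rms = rms,
                      mean_coherence = 0.8,
                      included = rep_len(included, length(sensors)),
                      stringsAsFactors = FALSE)
  structure(list(subject_id = subject_id, trials = NULL, means = means),
            class = "subject_outcomes")
}

fake_pair <- function(d, group = "Discordant", outcome = "PEAK", sensor = "L1",
                      pair_id = "P") {
  structure(list(pair_id = pair_id, concordance = group,
                 subjects = c("a", "b"),
                 differences = data.frame(sensor = sensor, outcome = outcome,
                                          difference = d,
                                          stringsAsFactors = FALSE)),
            class = "twin_pair_result")
}

test_that("pair differences are signed lower-id minus higher-id", {
  a <- fake_outcomes("P01-T1", peak = c(120, 90))
  b <- fake_outcomes("P01-T2", peak = c(100, 95))
  pr <- pair_differences(a, b)
  pk <- pr$differences[pr$differences$outcome == "PEAK", ]
  expect_equal(pk$difference[pk$sensor == "L1"], 20)
  expect_equal(pk$difference[pk$sensor == "L2"], -5)
  expect_equal(pr$pair_id, "P01")
  # order of arguments is immaterial: the id convention fixes the sign
  pr_swap <- pair_differences(b, a)
  expect_equal(pr_swap$differences, pr$differences)
  # identical twins: all differences zero
  pr0 <- pair_differences(a, fake_outcomes("P01-T2", peak = c(120, 90)))
  expect_true(all(pr0$differences$difference == 0))
})

test_that("differences are restricted to sensors included in both twins", {
  a <- fake_outcomes("x", c(1, 2), included = c(TRUE, FALSE))
  b <- fake_outcomes("y", c(1, 2), included = c(TRUE, TRUE))
  pr <- pair_differences(a, b)
  expect_equal(unique(pr$differences$sensor), "L1")
  c_ <- fake_outcomes("z", c(1, 2), included = FALSE)
  expect_error(pair_differences(a, c_), "no sensor passed QC")
})

test_that("group tests match the textbook one-sample t and handle degeneracy", {
  d <- c(1.2, 0.8, 1.5, 1.1, 0.9)
  res <- test_group_differences(list(fake_pair(d[1]), fake_pair(d[2]),
                                     fake_pair(d[3]), fake_pair(d[4]),
                                     fake_pair(d[5])))
  o <- oracle_one_sample_t(d)
  expect_equal(res$statistic, o$statistic, tolerance = 1e-10)
  expect_equal(res$p_value, o$p_value, tolerance = 1e-10)
  expect_equal(res$mean_difference, mean(d), tolerance = 1e-12)

  sym <- lapply(c(1, -1, 2, -2), fake_pair)
  res_sym <- test_group_differences(sym)
  expect_equal(res_sym$statistic, 0, tolerance = 1e-12)
  expect_equal(res_sym$p_value, 1)

  flat <- lapply(c(5, 5, 5, 5), fake_pair)
  expect_warning(res_flat <- test_group_differences(flat), "degenerate")
  expect_equal(res_flat$p_value, 1)
})

test_that("negating every difference leaves p-values unchanged", {
  set.seed(7)
  d <- rnorm(6, mean = 2)
  p1 <- test_group_differences(lapply(d, fake_pair))
  p2 <- test_group_differences(lapply(-d, fake_pair))
  expect_equal(p2$p_value, p1$p_value, tolerance = 1e-12)
  expect_equal(p2$mean_difference, -p1$mean_difference)
})

test_that("ancova on an intercept-only model reduces to the t-test", {
  d <- c(1.2, 0.8, 1.5, 1.1, 0.9)
  pairs <- lapply(d, fake_pair)
  t_res <- test_group_differences(pairs, method = "paired-t")
  a_res <- test_group_differences(pairs, method = "ancova")
  expect_equal(a_res$statistic, t_res$statistic, tolerance = 1e-10)
  expect_equal(a_res$p_value, t_res$p_value, tolerance = 1e-10)
  # with a centered covariate the intercept is still the adjusted group mean
  cov <- data.frame(bmi = c(20, 25, 30, 22, 28))
  a_cov <- test_group_differences(pairs, method = "ancova", covariates = cov)
  expect_equal(a_cov$mean_difference, mean(d), tolerance = 1e-10)
  expect_equal(a_cov$method, "ancova")
})

test_that("metadata parsing reproduces the twin-study roster counts", {
  tab <- system.file("extdata", "table1.tsv", package = "spinevib")
  md <- parse_metadata(tab)
  expect_equal(md$counts$n_subjects, 20L)
  expect_equal(md$counts$n_pairs, 10L)
  expect_equal(unname(md$counts$pairs_mri["Concordant"]), 4L, ignore_attr = TRUE)
  expect_equal(unname(md$counts$pairs_mri["Discordant"]), 6L, ignore_attr = TRUE)
  expect_equal(unname(md$counts$pairs_selfreport["Concordant"]), 5L,
               ignore_attr = TRUE)
  expect_equal(unname(md$counts$pairs_selfreport["Discordant"]), 5L,
               ignore_attr = TRUE)
})

test_that("metadata validation rejects malformed tables", {
  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(parse_metadata(empty), "empty")
  writeLines("subject_id\tpair_id", empty)
  expect_error(parse_metadata(empty), "missing column")
  bad <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,pair_id,sex,age,bmi,selfreport_concordance,mri_concordance",
               "1,1,F,40,22,Concordant,Concordant",
               "2,1,F,40,22,Concordant,Discordant",
               "3,2,M,41,23,Concordant,Concordant"), bad)
  expect_error(parse_metadata(bad), "exactly 2 subjects|conflicting")
  writeLines(c("subject_id,pair_id,sex,age,bmi,selfreport_concordance,mri_concordance",
               "1,1,F,40,22,Concordant,Concordant",
               "2,1,F,40,22,Concordant,Discordant"), bad)
  expect_error(parse_metadata(bad), "conflicting")
})

test_that("recruitment summary derives the survey response rate", {
  rec <- recruitment_summary(system.file("extdata", "recruitment.csv",
                                         package = "spinevib"))
  expect_equal(rec$response_rate_pct, 84.2)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("key,value", "individuals_approached,10",
               "individuals_responded,12"), bad)
  expect_error(recruitment_summary(bad), "more responders")
})

test_that("cohort reports have the full group x outcome x sensor grid", {
  coh <- generate_twin_cohort(2, 2, seed = 77)
  rep <- analyze_cohort(coh)
  expect_equal(nrow(rep$table), 2 * 3 * 4)
  expect_equal(sort(unique(rep$table$sensor)), c("L1", "L2", "L3", "L4"))
  expect_equal(sort(unique(rep$table$outcome)), c("AUC", "PEAK", "RMS"))
  expect_true(all(rep$table$p_value >= 0 & rep$table$p_value <= 1))
  expect_true(all(rep$table$n_pairs == 2))
})

test_that("within-pair |FRF difference| decreases with distance from the source", {
  # attenuation applies to both twins, so the FRF difference inherits the
  # distance-dependent gain ordering L1 > L2 > L3 > L4
  cfg <- short_cfg(2)
  drops <- vapply(1:6, function(r) {
    coh <- generate_twin_cohort(1, 0, cfg = cfg, seed = 500 + r, n_trials = 1)
    man <- coh$manifest
    sp <- lapply(coh$recordings[man$recording], analyze_recording,
                 band = short_band)
    d <- abs(sp[[1]]$frf[, 1:4] - sp[[2]]$frf[, 1:4])
    unname(colMeans(d))
  }, numeric(4))
  expect_true(all(diff(rowMeans(drops)) < 0))
})
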