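#' Within-pair outcome differences
#'
#' Signed difference (twin A minus twin B) of the trial-mean PEAK, AUC and
#' RMS outcomes per sensor, restricted to sensors that passed coherence QC
#' in both twins. Twin ordering is fixed by ascending subject id, so the
#' sign convention is reproducible.
#'
#' @param out_a,out_b `"subject_outcomes"` of the two twins.
#' @param pair_id Pair identifier; defaults to the common prefix of the two
#'   subject ids.
#' @param concordance Grouping label (`"Concordant"` or `"Discordant"`)
#'   carried into group-level testing.
#' @return Object of class `"twin_pair_result"`: list with `pair_id`,
#'   `concordance`, `subjects` (ordered ids) and `differences` (long
#'   data.frame: sensor, outcome in PEAK/AUC/RMS, difference).
#' @export
pair_differences <- function(out_a, out_b, pair_id = NULL,
                             concordance = NA_character_) {
  stopifnot(inherits(out_a, "subject_outcomes"),
            inherits(out_b, "subject_outcomes"))
  if (out_b$subject_id < out_a$subject_id) { tmp <- out_a; out_a <- out_b; out_b <- tmp }
  a <- out_a$means; b <- out_b$means
  common <- intersect(a$sensor[a$included], b$sensor[b$included])
  if (!length(common))
    stop("analysis error: no sensor passed QC in both twins of pair ",
         pair_id %||% "?")
  a <- a[match(common, a$sensor), ]; b <- b[match(common, b$sensor), ]
  diffs <- data.frame(
    sensor = rep(common, times = 3L),
    outcome = rep(c("PEAK", "AUC", "RMS"), each = length(common)),
    difference = c(a$peak_hz - b$peak_hz, a$auc - b$auc, a$rms - b$rms),
    stringsAsFactors = FALSE)
  structure(list(
    pair_id = pair_id %||% sub("-T\\d+$", "", out_a$subject_id),
    concordance = concordance,
    subjects = c(out_a$subject_id, out_b$subject_id),
    differences = diffs), class = "twin_pair_result")
}

#' @export
print.twin_pair_result <- function(x, ...) {
  cat(sprintf("<twin_pair_result> %s (%s): %s - %s\n", x$pair_id,
              x$concordance, x$subjects[1], x$subjects[2]))
  print(stats::xtabs(difference ~ outcome + sensor, data = x$differences),
        digits = 4)
  invisible(x)
}

# one-sample test of H0: mean(d) = 0; degenerate variance -> p = 1 + warning
one_sample_test <- function(d, method, covariates = NULL) {
  n <- length(d)
  if (n < 2L) stop("analysis error: need >= 2 pairs for a group test")
  if (stats::sd(d) < .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
    warning("degenerate variance in within-pair differences; p set to 1")
    return(list(statistic = NA_real_, p_value = 1, estimate = mean(d)))
  }
  if (method == "paired-t") {
    tt <- stats::t.test(d, mu = 0)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         estimate = unname(tt$estimate))
  } else { # ancova: differences on intercept + centered covariates
    dat <- data.frame(d = d)
    form <- "d ~ 1"
    if (!is.null(covariates) && ncol(covariates) > 0) {
      for (nm in colnames(covariates))
        dat[[nm]] <- covariates[[nm]] - mean(covariates[[nm]])
      form <- paste("d ~ 1 +", paste(colnames(covariates), collapse = " + "))
    }
    fit <- summary(stats::lm(stats::as.formula(form), data = dat))
    co <- fit$coefficients["(Intercept)", ]
    list(statistic = unname(co["t value"]), p_value = unname(co["Pr(>|t|)"]),
         estimate = unname(co["Estimate"]))
  }
}

#' Group-level tests of within-pair differences
#'
#' For each group x outcome x sensor cell, tests whether the mean
#' within-pair difference differs from zero. `"paired-t"` (default) is the
#' one-sample t-test on the pair differences — equivalent to the paired
#' t-test between twins. `"ancova"` fits a linear model of the differences
#' on an intercept plus (mean-centered) pair-level covariates and tests the
#' intercept. P-values are two-sided and reported uncorrected; an optional
#' Bonferroni adjustment across cells is available.
#'
#' @param pairs List of [pair_differences()] results.
#' @param method `"paired-t"` (default) or `"ancova"`.
#' @param covariates Optional data.frame of pair-level covariates (one row
#'   per pair, e.g. pair-mean BMI), used by the ANCOVA method.
#' @param bonferroni Apply Bonferroni correction across cells (default
#'   `FALSE`).
#' @return data.frame with one row per group x outcome x sensor:
#'   `group`, `outcome`, `sensor`, `n_pairs`, `mean_difference`,
#'   `statistic`, `p_value`, `significant` (p < 0.05), `method`.
#' @export
test_group_differences <- function(pairs, method = c("paired-t", "ancova"),
                                   covariates = NULL, bonferroni = FALSE) {
  method <- match.arg(method)
  stopifnot(length(pairs) > 0,
            all(vapply(pairs, inherits, logical(1), "twin_pair_result")))
  long <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    cbind(pair = i, group = pairs[[i]]$concordance, pairs[[i]]$differences,
          stringsAsFactors = FALSE)
  }))
  cells <- unique(long[c("group", "outcome", "sensor")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- long$group == cells$group[i] & long$outcome == cells$outcome[i] &
      long$sensor == cells$sensor[i]
    d <- long$difference[sel]
    if (length(d) < 2L) return(NULL)
    cov_i <- if (!is.null(covariates))
      covariates[long$pair[sel], , drop = FALSE]
    res <- one_sample_test(d, method, cov_i)
    data.frame(group = cells$group[i], outcome = cells$outcome[i],
               sensor = cells$sensor[i], n_pairs = length(d),
               mean_difference = res$estimate, statistic = res$statistic,
               p_value = res$p_value, method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_value <- pmin(1, out$p_value * nrow(out))
  out$significant <- out$p_value < 0.05
  out <- out[order(out$group, out$outcome, out$sensor),
             c("group", "outcome", "sensor", "n_pairs", "mean_difference",
               "statistic", "p_value", "significant", "method")]
  row.names(out) <- NULL
  out
}

#' Cohort-level difference report
#'
#' Runs the full comparison for a cohort: pairs subjects by `pair_id`,
#' computes within-pair differences of the trial-mean outcomes, and tests
#' each group x outcome x sensor cell. With the default chain and QC
#' threshold the most distal sensor fails coherence QC, leaving a
#' 2 groups x 3 outcomes x 4 sensors grid.
#'
#' @param outcomes List of `"subject_outcomes"`, one per subject.
#' @param metadata data.frame with at least `subject_id`, `pair_id` and a
#'   concordance column (`mri_concordance` preferred, else
#'   `selfreport_concordance`); `bmi` enables the default ANCOVA covariate.
#' @inheritParams test_group_differences
#' @return List of class `"cohort_report"`: `table` (the tested grid),
#'   `pairs` (list of `"twin_pair_result"`), `method`.
#' @export
cohort_report <- function(outcomes, metadata, method = c("paired-t", "ancova"),
                          bonferroni = FALSE) {
  method <- match.arg(method)
  ids <- vapply(outcomes, `[[`, character(1), "subject_id")
  if (!all(metadata$subject_id %in% ids))
    stop("analysis error: outcomes missing for subject(s) ",
         paste(setdiff(metadata$subject_id, ids), collapse = ", "))
  conc_col <- if ("mri_concordance" %in% names(metadata)) "mri_concordance"
  else "selfreport_concordance"
  pair_ids <- unique(metadata$pair_id)
  if (!length(pair_ids)) stop("analysis error: no pairs in metadata")
  pair_list <- list(); covs <- list()
  for (pid in pair_ids) {
    rowsel <- metadata[metadata$pair_id == pid, ]
    if (nrow(rowsel) != 2L)
      stop("validation error: pair ", pid, " does not have exactly 2 subjects")
    oa <- outcomes[[match(rowsel$subject_id[1], ids)]]
    ob <- outcomes[[match(rowsel$subject_id[2], ids)]]
    pair_list[[pid]] <- pair_differences(oa, ob, pair_id = pid,
                                         concordance = rowsel[[conc_col]][1])
    covs[[pid]] <- data.frame(
      bmi = if ("bmi" %in% names(rowsel)) mean(rowsel$bmi) else NA_real_)
  }
  covariates <- if (method == "ancova" && !anyNA(covs[[1]]$bmi))
    do.call(rbind, covs)
  tab <- test_group_differences(pair_list, method = method,
                                covariates = covariates,
                                bonferroni = bonferroni)
  structure(list(table = tab, pairs = pair_list, method = method),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %s, %d cells, %d pairs\n", x$method,
              nrow(x$table), length(x$pairs)))
  print(x$table, digits = 4)
  invisible(x)
}

#' Analyze a simulated twin cohort end to end
#'
#' Convenience pipeline from a [generate_twin_cohort()] result to a
#' [cohort_report()]: analyzes all trials per subject and compares twins.
#'
#' @param cohort A `"twin_cohort"`.
#' @inheritParams analyze_recording
#' @inheritParams summarize_subject
#' @inheritParams cohort_report
#' @return A `"cohort_report"`; the per-subject `"subject_outcomes"` are
#'   attached as attribute `"outcomes"`.
#' @export
analyze_cohort <- function(cohort, band = c(1, 2000), kernel_bins = 5,
                           convention = "power", qc_threshold = 0.5,
                           method = "paired-t") {
  stopifnot(inherits(cohort, "twin_cohort"))
  man <- cohort$manifest
  if (!nrow(man)) stop("analysis error: no pairs in cohort")
  subjects <- unique(man$subject_id)
  outcomes <- lapply(subjects, function(sid) {
    recs <- cohort$recordings[man$recording[man$subject_id == sid]]
    analyze_subject(recs, band = band, kernel_bins = kernel_bins,
                    convention = convention, qc_threshold = qc_threshold)
  })
  rep <- cohort_report(outcomes, cohort$metadata, method = method)
  attr(rep, "outcomes") <- outcomes
  rep
}

#' Parse a subject metadata table
#'
#' Reads a delimited subject table with the twin-study schema: one row per
#' subject with pair id, sex, age, BMI, concordance by self-report,
#' concordance by MRI and a status note. Validates that every pair has
#' exactly two subjects agreeing on MRI concordance, and derives the
#' recruitment-style counts.
#'
#' @param path Path to a tab- or comma-separated file with columns
#'   `subject_id`, `pair_id`, `sex`, `age`, `bmi`, `selfreport_concordance`,
#'   `mri_concordance`, and optionally `selfreport_note`, `mri_note`.
#' @return List with `subjects` (validated data.frame) and `counts`: a list
#'   with `n_subjects`, `n_pairs`, `pairs_selfreport` and `pairs_mri` (tables
#'   of pair counts by concordance label).
#' @examples
#' tab <- system.file("extdata", "table1.tsv", package = "spinevib")
#' parse_metadata(tab)$counts$pairs_mri
#' @export
parse_metadata <- function(path) {
  if (!file.exists(path)) stop("validation error: file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first))
    stop("validation error: empty metadata file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"")
  need <- c("subject_id", "pair_id", "sex", "age", "bmi",
            "selfreport_concordance", "mri_concordance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("validation error: metadata missing column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(df)) stop("validation error: metadata table has no rows")
  bad_lab <- setdiff(unique(c(df$selfreport_concordance, df$mri_concordance)),
                     c("Concordant", "Discordant"))
  if (length(bad_lab))
    stop("validation error: unknown concordance label(s): ",
         paste(bad_lab, collapse = ", "))
  sizes <- table(df$pair_id)
  if (any(sizes != 2L))
    stop("validation error: pair(s) without exactly 2 subjects: ",
         paste(names(sizes)[sizes != 2L], collapse = ", "))
  mri_per_pair <- tapply(df$mri_concordance, df$pair_id,
                         function(x) length(unique(x)))
  if (any(mri_per_pair != 1L))
    stop("validation error: conflicting MRI concordance within pair(s): ",
         paste(names(mri_per_pair)[mri_per_pair != 1L], collapse = ", "))
  pair_mri <- tapply(df$mri_concordance, df$pair_id, `[`, 1L)
  pair_self <- tapply(df$selfreport_concordance, df$pair_id,
                      function(x) if (length(unique(x)) == 1L) x[1] else "Mixed")
  list(subjects = df,
       counts = list(
         n_subjects = nrow(df),
         n_pairs = length(sizes),
         pairs_selfreport = table(pair_self),
         pairs_mri = table(pair_mri)))
}

#' Survey recruitment summary
#'
#' Reads a two-column key/value table of recruitment counts (individuals
#' approached and responding, presumed concordant/discordant complete pairs)
#' and derives the response rate.
#'
#' @param path CSV with columns `key`, `value`; must contain keys
#'   `individuals_approached` and `individuals_responded`.
#' @return List with the raw counts and `response_rate_pct` (rounded to one
#'   decimal, the convention used when reporting survey response rates).
#' @export
recruitment_summary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("key", "value") %in% names(df)))
    stop("validation error: recruitment file needs columns key,value")
  kv <- stats::setNames(df$value, df$key)
  need <- c("individuals_approached", "individuals_responded")
  if (any(!need %in% names(kv)))
    stop("validation error: recruitment file missing ",
         paste(setdiff(need, names(kv)), collapse = ", "))
  approached <- as.numeric(kv["individuals_approached"])
  responded <- as.numeric(kv["individuals_responded"])
  if (responded > approached)
    stop("validation error: more responders than approached individuals")
  c(as.list(kv),
    list(response_rate_pct = round(100 * responded / approached, 1)))
}
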