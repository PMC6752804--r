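# Synthetic longitudinal cohort generator.  Emulates the statistical
# structure the analysis assumes: three diagnostic groups (stable NL,
# stable MCI, AD converters with a stated conversion month), a cohort-study-like
# visit schedule with partial missingness, group-specific baseline volumes
# on the descriptive scale, linear atrophy/expansion trends with a
# mid-course rate change (acceleration) for converters, and measurement
# noise.  Volumes are simulated on the scaled analysis scale and emitted
# as raw mm^3 so the generated CSV matches the real-data input contract.

SYN_GROUPS <- c("converter", "stable_NL", "stable_MCI")
VOLS <- c("wholebrain", "hippocampus", "ventricles")
RAW_SCALE <- c(wholebrain = 1e6, hippocampus = 1e3, ventricles = 1e3)

group_matrix <- function(nl, mci, conv) {
  m <- rbind(converter = conv, stable_NL = nl, stable_MCI = mci)
  colnames(m) <- VOLS
  m
}

#' Parameters of the synthetic cohort generator
#'
#' Defaults encode the stated world the generator emulates: baseline
#' locations and spreads anchored to the descriptive medians/IQRs of the
#' three training groups (spread = IQR / 1.349, the normal IQR-to-SD
#' factor); atrophy/expansion rates such that converters lose about 1.07
#' scaled hippocampal units over 24 months (the cross-sectional AD-NL
#' baseline gap) while stable groups lose at most 20% of that; and an
#' extra hippocampus + whole-brain decline rate for converters that
#' switches on at `accel_onset_frac * conversion_month`, planting the
#' curvature that second-order signature terms detect (a purely linear
#' co-decline has zero Levy area).
#'
#' @param n_per_group Named counts for the training-style cohort.  Stable
#'   pools are generated larger than the 21 converters so that age
#'   matching retains all 21 cases.
#' @param n_per_group_test Named counts for the test-style cohort
#'   (10 converters, 20 stable NL, 6 stable MCI).
#' @param baseline_location,baseline_spread 3x3 matrices (group x volume),
#'   scaled units.
#' @param atrophy_rate 3x3 matrix of trend slopes, scaled units/month
#'   (negative = loss; ventricles expand).
#' @param baseline_family Per-volume sampling family for baselines:
#'   `"normal"` (truncated positive) or `"lognormal"` (location = median,
#'   spread treated as the SD-equivalent of the IQR; ventricles are
#'   right-skewed and use the lognormal).
#' @param ad_acceleration Extra converter slope (scaled units/month);
#'   zero for ventricles.  Where in the window it acts is set by
#'   `accel_phase`.
#' @param accel_phase Per-volume phase of the converter rate change,
#'   following the biomarker-cascade picture: `"early"` (hippocampus —
#'   extra decline from baseline up to the onset month, then easing as the
#'   trajectory approaches the floor of its sigmoid) or `"late"` (whole
#'   brain — extra decline from the onset month onward, as atrophy spreads
#'   to the rest of the brain).
#' @param accel_onset_frac Onset of the rate change as a fraction of the
#'   conversion month.
#' @param accel_onset_jitter Relative half-width of the per-subject
#'   uniform jitter on the onset month (disease-stage timing varies across
#'   subjects; the jitter is shared between volumes so the cascade shifts
#'   as a whole).
#' @param rate_sd Per-volume SD of the additive per-subject variation
#'   around the group trend slope (scaled units/month); independent across
#'   channels, identical across groups, emulating the wide individual
#'   variation of aging-related atrophy.
#' @param accel_cv Lognormal coefficient of variation of a converter's
#'   disease-severity factor, shared between the hippocampus and
#'   whole-brain accelerations so that the two decline jointly.
#' @param visit_months Measurement schedule (months).
#' @param visit_missing_prob Per-month probability that a measurement visit
#'   is dropped wholesale (month 3 is mostly missing; month 18 partially;
#'   months 24 and 36 are never dropped, see `forced_months`).
#' @param forced_months Months never dropped.
#' @param measurement_noise_sd Per-volume measurement noise SD (scaled
#'   units).
#' @param dx_months Diagnosis visit schedule (reaches the 84-month
#'   stability horizon).
#' @param age_range Uniform baseline age range in years.
#' @param conversion_month,test_conversion_month First-AD month for
#'   converters in the training-style and test-style cohorts.
#' @param pre_conversion_mci_prob Probability a converter carries an MCI
#'   (rather than NL) label before conversion (19 of 21 in the training
#'   description).
#' @param apoe4_probs 3x3 matrix (group x allele count 0/1/2).
#' @param male_prob Per-group probability of male gender.
#' @param seed Optional integer seed consumed by [generate_cohort()].
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(
    n_per_group = c(converter = 21L, stable_NL = 35L, stable_MCI = 35L),
    n_per_group_test = c(converter = 10L, stable_NL = 20L, stable_MCI = 6L),
    baseline_location = group_matrix(nl = c(1.02, 7.21, 28.53),
                                     mci = c(1.00, 7.10, 33.88),
                                     conv = c(1.00, 6.14, 34.34)),
    baseline_spread = group_matrix(nl = c(0.13, 1.23, 18.55) / 1.349,
                                   mci = c(0.12, 0.89, 26.78) / 1.349,
                                   conv = c(0.12, 1.41, 21.17) / 1.349),
    atrophy_rate = group_matrix(nl = c(-0.0002, -0.006, 0.06),
                                mci = c(-0.00035, -0.0085, 0.08),
                                conv = c(-0.0005, -0.0185, 0.13)),
    baseline_family = c(wholebrain = "normal", hippocampus = "normal",
                        ventricles = "lognormal"),
    ad_acceleration = c(wholebrain = -0.0021, hippocampus = -0.0347,
                        ventricles = 0),
    accel_phase = c(wholebrain = "late", hippocampus = "early",
                    ventricles = "late"),
    accel_onset_frac = 0.5,
    accel_onset_jitter = 0.25,
    rate_sd = c(wholebrain = 0.0012, hippocampus = 0.018, ventricles = 0.09),
    accel_cv = 0.4,
    visit_months = c(0, 3, 6, 12, 18, 24, 36, 48),
    visit_missing_prob = c(`0` = 0.05, `3` = 0.85, `6` = 0.05, `12` = 0.05,
                           `18` = 0.30, `24` = 0, `36` = 0, `48` = 0.05),
    forced_months = c(24, 36),
    measurement_noise_sd = c(wholebrain = 0.004, hippocampus = 0.12,
                             ventricles = 0.35),
    dx_months = c(0, 6, 12, 18, 24, 36, 48, 60, 72, 84),
    age_range = c(61, 90),
    conversion_month = 36, test_conversion_month = 48,
    pre_conversion_mci_prob = 19 / 21,
    apoe4_probs = rbind(converter = c(0.29, 0.52, 0.19),
                        stable_NL = c(0.81, 0.19, 0),
                        stable_MCI = c(0.71, 0.29, 0)),
    male_prob = c(converter = 10 / 21, stable_NL = 8 / 21,
                  stable_MCI = 13 / 21),
    seed = NULL) {
  p <- list(n_per_group = n_per_group, n_per_group_test = n_per_group_test,
            baseline_location = baseline_location,
            baseline_spread = baseline_spread,
            baseline_family = baseline_family, atrophy_rate = atrophy_rate,
            ad_acceleration = ad_acceleration, accel_phase = accel_phase,
            accel_onset_frac = accel_onset_frac,
            accel_onset_jitter = accel_onset_jitter,
            rate_sd = rate_sd, accel_cv = accel_cv,
            visit_months = visit_months,
            visit_missing_prob = visit_missing_prob,
            forced_months = forced_months,
            measurement_noise_sd = measurement_noise_sd,
            dx_months = dx_months, age_range = age_range,
            conversion_month = conversion_month,
            test_conversion_month = test_conversion_month,
            pre_conversion_mci_prob = pre_conversion_mci_prob,
            apoe4_probs = apoe4_probs, male_prob = male_prob, seed = seed)
  stopifnot(
    all(p$baseline_spread >= 0),
    all(p$measurement_noise_sd >= 0),
    all(p$visit_missing_prob >= 0 & p$visit_missing_prob <= 1),
    all(diff(p$visit_months) > 0), all(diff(p$dx_months) > 0),
    all(p$baseline_family %in% c("normal", "lognormal")),
    all(p$accel_phase %in% c("early", "late")),
    p$accel_onset_jitter >= 0 && p$accel_onset_jitter <= 1,
    all(p$rate_sd >= 0), p$accel_cv >= 0,
    p$accel_onset_frac >= 0 && p$accel_onset_frac <= 1,
    p$pre_conversion_mci_prob >= 0 && p$pre_conversion_mci_prob <= 1
  )
  structure(p, class = "cohort_params")
}

#' Null-world parameters: no group differences
#'
#' All three groups share the stable-NL baselines and trend rates and the
#' converter acceleration is zero, so diagnostic labels are independent of
#' the measured trajectories.  Used for null-calibration checks.
#'
#' @param ... Overrides passed on to [cohort_params()].
#' @return A `cohort_params` object.
#' @export
null_cohort_params <- function(...) {
  p <- cohort_params(...)
  nl_base <- p$baseline_location["stable_NL", ]
  nl_spread <- p$baseline_spread["stable_NL", ]
  nl_rate <- p$atrophy_rate["stable_NL", ]
  for (g in SYN_GROUPS) {
    p$baseline_location[g, ] <- nl_base
    p$baseline_spread[g, ] <- nl_spread
    p$atrophy_rate[g, ] <- nl_rate
  }
  p$ad_acceleration[] <- 0
  p
}

lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sl <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sl^2 / 2, sl))  # mean-1 lognormal
}

#' Generate one synthetic subject
#'
#' Draws baseline volumes from group-specific truncated normals, a latent
#' piecewise-linear trajectory (group trend, plus the converter
#' acceleration on hippocampus and whole brain from the onset month), adds
#' measurement noise per visit, drops visits by the per-month missingness
#' (forced months exempt), and lays down the diagnosis series (converters
#' switch to AD at `conversion_month`; stable groups hold their label
#' across the diagnosis schedule).  Consumes the current RNG stream.
#'
#' @param group One of `"converter"`, `"stable_NL"`, `"stable_MCI"`.
#' @param params A [cohort_params()] object.
#' @param subject_id Id for the record.
#' @param conversion_month First-AD month (defaults to the training value).
#' @return A `subject_record` (measurements in raw mm^3 units).
#' @export
generate_subject <- function(group, params, subject_id = "S001",
                             conversion_month = params$conversion_month) {
  if (!group %in% SYN_GROUPS)
    stop(sprintf("unknown group '%s'", group), call. = FALSE)
  age <- runif(1, params$age_range[1L], params$age_range[2L])
  gender <- if (rbinom(1, 1, params$male_prob[[group]]) == 1) "M" else "F"
  apoe4 <- sample(0:2, 1L, prob = params$apoe4_probs[group, ])
  base <- numeric(3)
  for (v in 1:3) {
    loc <- params$baseline_location[group, v]
    spr <- params$baseline_spread[group, v]
    if (params$baseline_family[[v]] == "lognormal") {
      # location = median; spread mapped to the log scale via the
      # coefficient of variation, keeping the printed IQR scale
      sdlog <- sqrt(log(1 + (spr / loc)^2))
      base[v] <- exp(rnorm(1, log(loc), sdlog))
    } else {
      repeat {
        b <- rnorm(1, loc, spr)
        if (b > 0) break
      }
      base[v] <- b
    }
  }
  rates <- params$atrophy_rate[group, ] + rnorm(3, 0, params$rate_sd)
  accel <- if (group == "converter") {
    # one severity factor: hippocampus and whole brain accelerate jointly
    params$ad_acceleration * lognormal_factor(1, params$accel_cv)
  } else c(wholebrain = 0, hippocampus = 0, ventricles = 0)
  onset <- params$accel_onset_frac * conversion_month *
    runif(1, 1 - params$accel_onset_jitter, 1 + params$accel_onset_jitter)

  vm <- params$visit_months
  miss_p <- params$visit_missing_prob[as.character(vm)]
  miss_p[is.na(miss_p)] <- 0
  present <- vm %in% params$forced_months | runif(length(vm)) >= miss_p
  meas_months <- vm[present]
  accel_time <- function(v, t) {
    if (params$accel_phase[[v]] == "early") pmin(t, onset) else pmax(0, t - onset)
  }
  latent <- vapply(1:3, function(v)
    base[v] + rates[v] * meas_months + accel[v] * accel_time(v, meas_months),
    numeric(length(meas_months)))
  latent <- matrix(latent, ncol = 3L)
  noise <- vapply(1:3, function(v)
    rnorm(length(meas_months), 0, params$measurement_noise_sd[v]),
    numeric(length(meas_months)))
  obs <- latent + matrix(noise, ncol = 3L)

  dm <- params$dx_months
  dx <- if (group == "converter") {
    pre <- if (runif(1) < params$pre_conversion_mci_prob) "MCI" else "NL"
    ifelse(dm >= conversion_month, "AD", pre)
  } else if (group == "stable_NL") rep("NL", length(dm)) else
    rep("MCI", length(dm))

  months <- sort(unique(c(meas_months, dm)))
  vol <- matrix(NA_real_, nrow = length(months), ncol = 3L)
  vol[match(meas_months, months), ] <- obs
  vol <- sweep(vol, 2L, RAW_SCALE, "*")
  dx_all <- rep(NA_character_, length(months))
  dx_all[match(dm, months)] <- dx

  subject_record(
    subject_id = subject_id, age = age, gender = gender, apoe4 = apoe4,
    diagnoses = data.frame(month = dm, dx = dx, stringsAsFactors = FALSE),
    measurements = data.frame(month = months, wholebrain = vol[, 1L],
                              hippocampus = vol[, 2L], ventricles = vol[, 3L])
  )
}

record_to_visits <- function(record) {
  m <- record$measurements
  dx <- rep(NA_character_, nrow(m))
  hit <- match(record$diagnoses$month, m$month)
  dx[hit[!is.na(hit)]] <- record$diagnoses$dx[!is.na(hit)]
  data.frame(subject_id = record$subject_id, month = m$month, dx = dx,
             wholebrain = m$wholebrain, hippocampus = m$hippocampus,
             ventricles = m$ventricles, age = record$age,
             gender = record$gender, apoe4 = record$apoe4,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Generates a full training-style cohort (conversion at
#' `params$conversion_month`, 72-month stability reachable) or test-style
#' cohort (conversion at `params$test_conversion_month`, 84-month
#' stability), deterministic given `params$seed`.
#'
#' @param params A [cohort_params()] object.
#' @param cohort `"training"` or `"test"`.
#' @param id_prefix Subject id prefix (default `"TR"` / `"TE"`), keeping
#'   training and test ids disjoint.
#' @return An object of class `synthetic_cohort`: a list with `records`
#'   (named list of `subject_record`), `groups` (named ground-truth
#'   labels), `visits` (the standard longitudinal table, raw volumes) and
#'   `conversion_month`.
#' @export
generate_cohort <- function(params = cohort_params(),
                            cohort = c("training", "test"),
                            id_prefix = NULL) {
  cohort <- match.arg(cohort)
  if (!is.null(params$seed)) set.seed(params$seed)
  conversion <- if (cohort == "training") params$conversion_month else
    params$test_conversion_month
  n <- if (cohort == "training") params$n_per_group else params$n_per_group_test
  if (is.null(id_prefix)) id_prefix <- if (cohort == "training") "TR" else "TE"
  records <- list()
  groups <- character(0)
  counter <- 0L
  for (g in SYN_GROUPS) {
    for (i in seq_len(n[[g]])) {
      counter <- counter + 1L
      id <- sprintf("%s%03d", id_prefix, counter)
      records[[id]] <- generate_subject(g, params, id, conversion)
      groups[id] <- g
    }
  }
  visits <- do.call(rbind, lapply(records, record_to_visits))
  rownames(visits) <- NULL
  structure(
    list(records = records, groups = groups, visits = visits,
         cohort = cohort, conversion_month = conversion, params = params),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %s: %s\n", x$cohort,
              paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a cohort's visit table as CSV
#'
#' @param x A `synthetic_cohort` or a visits data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(x, path) {
  df <- if (inherits(x, "synthetic_cohort")) x$visits else x
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
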