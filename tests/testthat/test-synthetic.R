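test_that("cohort generation is deterministic and round-trips through CSV", {
  p <- cohort_params(seed = 77)
  c1 <- generate_cohort(p, "training")
  c2 <- generate_cohort(p, "training")
  expect_identical(c1$visits, c2$visits)
  expect_identical(c1$groups, c2$groups)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_visits(c1, f1); write_visits(c2, f2)
  expect_identical(readLines(f1), readLines(f2))

  recs <- read_longitudinal_table(f1)
  expect_setequal(names(recs), names(c1$records))
  id <- names(c1$records)[1]
  expect_equal(recs[[id]]$age, c1$records[[id]]$age, tolerance = 1e-8)
  expect_equal(recs[[id]]$diagnoses, c1$records[[id]]$diagnoses)
  expect_equal(recs[[id]]$measurements, c1$records[[id]]$measurements,
               tolerance = 1e-8)
  unlink(c(f1, f2))
})

test_that("baseline draws sit on the descriptive scale of the three groups", {
  p <- cohort_params()
  set.seed(1)
  med_bl <- function(group, n = 400) {
    vals <- vapply(seq_len(n), function(i) {
      r <- generate_subject(group, p, "S")
      m <- r$measurements
      ok <- is.finite(m$hippocampus)
      m$hippocampus[ok][which.min(m$month[ok])] / 1e3
    }, numeric(1))
    median(vals)
  }
  expect_lt(abs(med_bl("converter") - 6.14) / 6.14, 0.10)
  expect_lt(abs(med_bl("stable_NL") - 7.21) / 7.21, 0.10)
})

test_that("a noiseless, trend-free world yields constant trajectories", {
  p <- cohort_params(seed = 2)
  p$atrophy_rate[] <- 0
  p$ad_acceleration[] <- 0
  p$rate_sd[] <- 0
  p$measurement_noise_sd[] <- 0
  p$visit_missing_prob[] <- 0
  set.seed(2)
  r <- generate_subject("stable_NL", p, "S")
  m <- r$measurements[is.finite(r$measurements$hippocampus), ]
  expect_equal(diff(range(m$hippocampus)), 0)
  expect_equal(diff(range(m$wholebrain)), 0)
  w <- extract_window(r, 0, 24)
  fv <- build_feature_vector(time_augment(w), "signature")
  zero <- setdiff(fv$names, c("Wholebrain_BL", "Hippocampus_BL",
                              "Ventricles_BL", "(Incr. Time)", "(Time, Time)"))
  expect_true(all(abs(fv$values[match(zero, fv$names)]) < 1e-9))
})

test_that("noise-free converters show the planted path geometry", {
  p <- cohort_params()
  p$measurement_noise_sd[] <- 0
  p$rate_sd[] <- 0
  p$visit_missing_prob[] <- 0
  set.seed(42)
  areas <- incr_h <- incr_w <- numeric(30)
  for (i in 1:30) {
    r <- generate_subject("converter", p, "S")
    fv <- build_feature_vector(time_augment(extract_window(r, 0, 24)),
                               "log_signature")
    areas[i] <- fv$values[match("[Wholebrain, Hippocampus]", fv$names)]
    incr_w[i] <- fv$values[match("[Incr. Wholebrain]", fv$names)]
    incr_h[i] <- fv$values[match("[Incr. Hippocampus]", fv$names)]
  }
  # both volumes decline; the hippocampus-leading cascade fixes the area sign
  expect_true(all(incr_h < 0) && all(incr_w < 0))
  expect_true(all(areas < 0) || all(areas > 0))

  # with full noise, most converters should still show a
  # positive (Hippocampus, Wholebrain) signature term
  pd <- cohort_params()
  set.seed(43)
  s_hw <- numeric(0)
  while (length(s_hw) < 40) {
    r <- generate_subject("converter", pd, "S")
    w <- extract_window(r, 0, 24)
    if (is_rejected(w)) next  # default missingness can thin a window
    fv <- build_feature_vector(time_augment(w), "signature")
    s_hw <- c(s_hw, fv$values[match("(Hippocampus, Wholebrain)", fv$names)])
  }
  expect_gt(mean(s_hw > 0), 0.5)
})

test_that("cohort filters recover the planted partition without missingness", {
  p <- cohort_params(seed = 9)
  p$visit_missing_prob[] <- 0
  for (kind in c("training", "test")) {
    sim <- generate_cohort(p, kind)
    conv_month <- if (kind == "training") 36 else 48
    stab <- if (kind == "training") 72 else 84
    got <- vapply(sim$records, classify_trajectory, character(1),
                  conv_month, stab)
    expect_identical(unname(got), unname(sim$groups))
  }
})

test_that("test accuracy responds to the planted acceleration dose", {
  accs <- vapply(c(0, 0.5, 1), function(mult) {
    mean(vapply(1:3, function(s) {
      p <- null_cohort_params(
        n_per_group = c(converter = 12L, stable_NL = 18L, stable_MCI = 18L),
        n_per_group_test = c(converter = 8L, stable_NL = 12L,
                             stable_MCI = 6L))
      p$ad_acceleration <- c(wholebrain = -0.0021, hippocampus = -0.0347,
                             ventricles = 0) * mult
      cfg <- run_config(seed = 100 + s, params = p,
                        representation = "signature")
      r <- suppressMessages(suppressWarnings(run_pipeline(cfg)))
      mean(c(r$results$signature$AD_vs_NL$balanced_accuracy,
             r$results$signature$AD_vs_MCI$balanced_accuracy))
    }, numeric(1)))
  }, numeric(1))
  expect_gte(accs[2], accs[1] - 0.03)
  expect_gte(accs[3], accs[2] - 0.03)
  expect_gt(accs[3], accs[1] + 0.05)
})
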