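make_record <- function(id = "S1", months = c(0, 6, 12, 18, 24),
                        wb = NULL, hipp = NULL, vent = NULL, age = 75) {
  n <- length(months)
  if (is.null(wb)) wb <- rep(1.0e6, n)
  if (is.null(hipp)) hipp <- rep(7000, n)
  if (is.null(vent)) vent <- rep(30000, n)
  subject_record(
    id, age, "F", 0L,
    diagnoses = data.frame(month = months, dx = rep("NL", n)),
    measurements = data.frame(month = months, wholebrain = wb,
                              hippocampus = hipp, ventricles = vent)
  )
}

test_that("volume scaling maps raw mm^3 onto the descriptive scale", {
  sv <- scale_volumes(1.00e6, 7210, 28530)
  expect_equal(unlist(sv, use.names = FALSE), c(1.00, 7.21, 28.53))
  expect_equal(unlist(scale_volumes(1e6, 1e3, 1e3), use.names = FALSE),
               c(1, 1, 1))
  expect_error(scale_volumes(0, 7000, 30000), "positive")
})

test_that("window extraction applies the completeness and endpoint rules", {
  p <- extract_window(make_record(), 0, 24, 4, TRUE)
  expect_s3_class(p, "labeled_path")
  expect_equal(length(p$times), 5L)
  expect_equal(p$channel_names, c("Wholebrain", "Hippocampus", "Ventricles"))

  few <- extract_window(make_record(months = c(0, 6, 12)), 0, 24, 4, TRUE)
  expect_true(is_rejected(few))
  expect_match(few$reason, "too few")

  noend <- extract_window(make_record(months = c(0, 6, 12, 18)), 0, 24, 4, TRUE)
  expect_true(is_rejected(noend))
  expect_match(noend$reason, "endpoint")

  # a visit missing one channel is dropped wholesale
  r <- make_record(hipp = c(7000, NA, 7000, 7000, 7000))
  p2 <- extract_window(r, 0, 24, 4, TRUE)
  expect_equal(length(p2$times), 4L)
})

test_that("time augmentation appends raw months as a channel", {
  p <- time_augment(extract_window(make_record(), 0, 24))
  expect_equal(p$channel_names[4], "Time")
  expect_equal(p$values[, 4], c(0, 6, 12, 18, 24))
  # time increment over the training window
  expect_equal(unname(compute_signature(p, 2)$levels[[2]][4]), 24)
})

test_that("feature vectors have the documented layout and length", {
  r <- make_record(wb = seq(1.02e6, 1.00e6, length.out = 5),
                   hipp = seq(7200, 6800, length.out = 5),
                   vent = seq(28000, 30000, length.out = 5))
  p <- time_augment(extract_window(r, 0, 24))
  fv <- build_feature_vector(p, "signature", "S1")
  expect_length(fv$values, 23L)
  expect_equal(fv$names[1:7],
               c("Wholebrain_BL", "Hippocampus_BL", "Ventricles_BL",
                 "(Incr. Time)", "(Incr. Wholebrain)", "(Incr. Hippocampus)",
                 "(Incr. Ventricles)"))
  expect_true(all(c("(Hippocampus, Time)", "(Hippocampus, Wholebrain)") %in%
                    fv$names))
  expect_equal(unname(fv$values[4]), 24)

  lv <- build_feature_vector(p, "log_signature", "S1")
  expect_length(lv$values, 13L)
  expect_true(all(c("Hippocampus_BL", "[Incr. Hippocampus]",
                    "[Hippocampus, Time]") %in% lv$names))

  # constant volumes: everything vanishes except baselines and pure-Time terms
  cp <- time_augment(extract_window(make_record(), 0, 24))
  cf <- build_feature_vector(cp, "signature")
  nz <- cf$names[abs(cf$values) > 1e-12]
  expect_setequal(nz, c("Wholebrain_BL", "Hippocampus_BL", "Ventricles_BL",
                        "(Incr. Time)", "(Time, Time)"))

  bad <- labeled_path(0:1, matrix(1, 2, 3), c("A", "B", "C"))
  expect_error(build_feature_vector(time_augment(bad)), "channels")
})

test_that("area features inherit translation invariance in time", {
  r <- make_record(hipp = c(7200, 7100, 6950, 6800, 6600))
  p1 <- time_augment(extract_window(r, 0, 24))
  p2 <- labeled_path(p1$times, cbind(p1$values[, 1:3], p1$times + 120),
                     p1$channel_names)
  f1 <- build_feature_vector(p1, "log_signature")
  f2 <- build_feature_vector(p2, "log_signature")
  i <- match("[Hippocampus, Time]", f1$names)
  expect_equal(f1$values[i], f2$values[i], tolerance = 1e-10)
})

test_that("featurize_records returns a matrix plus typed rejections", {
  recs <- list(A = make_record("A"),
               B = make_record("B", months = c(0, 6, 12)))
  out <- featurize_records(recs)
  expect_equal(rownames(out$x), "A")
  expect_equal(ncol(out$x), 23L)
  expect_named(out$rejected, "B")
})
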