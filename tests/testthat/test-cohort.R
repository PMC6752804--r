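visit_df <- function(ids, months, dx = "NL", age = 75) {
  do.call(rbind, lapply(ids, function(id)
    data.frame(subject_id = id, month = months,
               dx = dx, wholebrain = 1e6, hippocampus = 7e3,
               ventricles = 3e4, age = age, gender = "F", apoe4 = 0)))
}

dx_record <- function(months, labels, id = "S1", age = 75) {
  subject_record(id, age, "F", 0L,
                 diagnoses = data.frame(month = months, dx = labels),
                 measurements = data.frame(month = numeric(0),
                                           wholebrain = numeric(0),
                                           hippocampus = numeric(0),
                                           ventricles = numeric(0)))
}

test_that("longitudinal tables parse into one record per subject", {
  df <- visit_df(c("A", "B", "C"), c(0, 6, 12, 18, 24))
  recs <- read_longitudinal_table(df)
  expect_length(recs, 3L)
  expect_equal(nrow(recs$A$measurements), 5L)
  expect_equal(nrow(recs$A$diagnoses), 5L)
  expect_equal(recs$B$age, 75)

  # duplicated (subject, month): last wins with a warning
  dup <- rbind(df, transform(df[1, ], hippocampus = 1234))
  expect_warning(recs2 <- read_longitudinal_table(dup), "duplicated")
  expect_equal(recs2$A$measurements$hippocampus[1], 1234)

  # unparseable month rows dropped with a warning
  bad <- df
  bad$month <- as.character(bad$month)
  bad$month[3] <- "not-a-month"
  expect_warning(recs3 <- read_longitudinal_table(bad), "unparseable")
  expect_equal(nrow(recs3$A$measurements), 4L)

  expect_error(read_longitudinal_table(df[, -3]), "dx")
  expect_error(read_longitudinal_table(df[0, ]), "no data rows")
})

test_that("trajectory classification follows the conversion/stability rules", {
  conv <- dx_record(c(0, 12, 24, 36), c("MCI", "MCI", "MCI", "AD"))
  expect_equal(classify_trajectory(conv, 36, 72), "converter")

  early <- dx_record(c(0, 24), c("MCI", "AD"))
  expect_equal(classify_trajectory(early, 36, 72), "other")

  nl <- dx_record(seq(0, 72, 12), rep("NL", 7))
  expect_equal(classify_trajectory(nl, 36, 72), "stable_NL")

  short <- dx_record(seq(0, 60, 12), rep("NL", 6))
  expect_equal(classify_trajectory(short, 36, 84), "other")

  revert <- dx_record(c(0, 12, 24, 72), c("MCI", "NL", "MCI", "MCI"))
  expect_equal(classify_trajectory(revert, 36, 72), "other")
})

test_that("greedy age matching is deterministic with stated tie-breaks", {
  mk <- function(id, age) dx_record(c(0, 72), c("NL", "NL"), id, age)
  cases <- list(C1 = mk("C1", 75))
  nl <- list(N1 = mk("N1", 71), N2 = mk("N2", 79), N3 = mk("N3", 86))
  mci <- list(M1 = mk("M1", 74))
  m <- match_controls(cases, nl, mci, 5)
  expect_length(m, 1L)
  # |75-71| == |75-79| == 4: tie broken by the smaller id
  expect_equal(m[[1]]$nl, "N1")

  far <- suppressMessages(
    match_controls(cases, list(N1 = mk("N1", 81)), mci, 5))
  expect_length(far, 0L)
  expect_named(attr(far, "dropped"), "C1")

  # matching consumes controls without replacement, ascending case id
  cases2 <- list(C2 = mk("C2", 70), C1 = mk("C1", 70))
  nl2 <- list(N1 = mk("N1", 70), N2 = mk("N2", 74))
  mci2 <- list(M1 = mk("M1", 70), M2 = mk("M2", 70))
  m2 <- match_controls(cases2, nl2, mci2, 5)
  expect_equal(vapply(m2, `[[`, character(1), "ad"), c("C1", "C2"))
  expect_equal(vapply(m2, `[[`, character(1), "nl"), c("N1", "N2"))
})

test_that("test-set assembly enforces disjointness and the 84-month rule", {
  p <- cohort_params(seed = 5)
  sim <- generate_cohort(p, "test", id_prefix = "TE")
  ts <- build_test_sets(sim$records, train_ids = "somebody-else")
  expect_true(all(ts$groups %in% c("converter", "stable_NL", "stable_MCI")))
  expect_gt(length(ts$records), 0L)

  expect_error(
    build_test_sets(sim$records, train_ids = names(ts$records)[1]),
    "overlap")

  # stable subject observed only to month 60 misses the 84-month horizon
  short <- dx_record(seq(0, 60, 12), rep("NL", 6), "SH")
  expect_equal(classify_trajectory(short, 48, 84), "other")
})
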