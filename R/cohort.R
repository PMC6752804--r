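# Cohort handling: longitudinal CSV -> subject records, trajectory-based
# group labels, training/test inclusion filters, greedy age matching.

DX_LEVELS <- c("NL", "MCI", "AD")

#' Construct a subject record
#'
#' One subject's diagnosis trajectory, visit measurements and baseline
#' demographics.  Measurements are kept in raw units (mm^3); scaling
#' happens at feature-extraction time.
#'
#' @param subject_id Character id.
#' @param age Baseline age in years.
#' @param gender `"M"`/`"F"` (or `NA`).
#' @param apoe4 APOE4 allele count, 0/1/2 (or `NA`).
#' @param diagnoses Data frame with columns `month` (strictly increasing,
#'   non-negative) and `dx` (one of `NL`, `MCI`, `AD`).
#' @param measurements Data frame with columns `month`, `wholebrain`,
#'   `hippocampus`, `ventricles`; any volume may be `NA`.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, age, gender = NA_character_,
                           apoe4 = NA_integer_, diagnoses, measurements) {
  check_months <- function(m, what) {
    if (any(!is.finite(m)) || any(m < 0))
      stop(sprintf("%s months must be finite and non-negative", what),
           call. = FALSE)
    if (length(m) > 1L && any(diff(m) <= 0))
      stop(sprintf("%s months must be strictly increasing", what),
           call. = FALSE)
  }
  diagnoses <- as.data.frame(diagnoses)
  measurements <- as.data.frame(measurements)
  if (nrow(diagnoses)) {
    check_months(diagnoses$month, "diagnosis")
    if (any(!diagnoses$dx %in% DX_LEVELS))
      stop("diagnosis labels must be one of NL, MCI, AD", call. = FALSE)
  }
  if (nrow(measurements)) check_months(measurements$month, "measurement")
  structure(
    list(subject_id = as.character(subject_id), age = as.numeric(age),
         gender = gender, apoe4 = apoe4,
         diagnoses = diagnoses, measurements = measurements),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s, age %.1f, %d dx visits, %d measurement visits\n",
              x$subject_id, x$age, nrow(x$diagnoses), nrow(x$measurements)))
  invisible(x)
}

#' Read a longitudinal visit table into subject records
#'
#' Reads a flat one-row-per-subject-visit table (flat study-export style)
#' with subject id, visit month, diagnosis and raw volumes, plus baseline
#' age, gender and APOE4.  Rows with unparseable months are dropped with a
#' warning; duplicated (subject, month) rows are resolved last-wins with a
#' warning.
#'
#' @param source A CSV file path or a data frame.
#' @param columns Named character vector mapping the required fields
#'   (`subject_id`, `month`, `dx`, `wholebrain`, `hippocampus`,
#'   `ventricles`, `age`, `gender`, `apoe4`) to the table's column names.
#' @return A named list of [subject_record()] objects, ordered by id.
#' @export
read_longitudinal_table <- function(source, columns = NULL) {
  default_cols <- c(subject_id = "subject_id", month = "month", dx = "dx",
                    wholebrain = "wholebrain", hippocampus = "hippocampus",
                    ventricles = "ventricles", age = "age", gender = "gender",
                    apoe4 = "apoe4")
  if (!is.null(columns)) default_cols[names(columns)] <- columns
  cols <- default_cols
  df <- if (is.data.frame(source)) source else
    read.csv(source, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("longitudinal table has no data rows", call. = FALSE)
  missing_cols <- setdiff(unname(cols), names(df))
  if (length(missing_cols))
    stop(sprintf("longitudinal table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  month <- suppressWarnings(as.numeric(df[[cols["month"]]]))
  bad <- !is.finite(month)
  if (any(bad)) {
    warning(sprintf("dropping %d row(s) with unparseable month", sum(bad)),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    month <- month[!bad]
  }
  id <- as.character(df[[cols["subject_id"]]])
  dup <- duplicated(cbind(id, month), fromLast = TRUE)
  if (any(dup)) {
    warning(sprintf("%d duplicated (subject, month) row(s); keeping the last",
                    sum(dup)), call. = FALSE)
    df <- df[!dup, , drop = FALSE]
    month <- month[!dup]
    id <- id[!dup]
  }
  dx_raw <- as.character(df[[cols["dx"]]])
  unknown <- !is.na(dx_raw) & nzchar(dx_raw) & !dx_raw %in% DX_LEVELS
  if (any(unknown)) {
    warning(sprintf("%d row(s) with unknown diagnosis code treated as missing",
                    sum(unknown)), call. = FALSE)
    dx_raw[unknown] <- NA_character_
  }
  dx_raw[!is.na(dx_raw) & !nzchar(dx_raw)] <- NA_character_
  num <- function(field) suppressWarnings(as.numeric(df[[cols[field]]]))
  tab <- data.frame(
    subject_id = id, month = month, dx = dx_raw,
    wholebrain = num("wholebrain"), hippocampus = num("hippocampus"),
    ventricles = num("ventricles"), age = num("age"),
    gender = as.character(df[[cols["gender"]]]),
    apoe4 = suppressWarnings(as.integer(df[[cols["apoe4"]]])),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$subject_id, tab$month), , drop = FALSE]
  records <- lapply(split(tab, tab$subject_id), function(s) {
    dxs <- s[!is.na(s$dx), c("month", "dx")]
    subject_record(
      subject_id = s$subject_id[1L],
      age = s$age[1L], gender = s$gender[1L], apoe4 = s$apoe4[1L],
      diagnoses = dxs,
      measurements = s[, c("month", "wholebrain", "hippocampus", "ventricles")]
    )
  })
  records[order(names(records))]
}

#' Classify a subject's diagnosis trajectory
#'
#' A subject is a `converter` if their first AD diagnosis occurs exactly at
#' `conversion_month` (earlier visits non-AD); `stable_NL` / `stable_MCI`
#' if every diagnosis in `[0, stability_months]` is NL / MCI and the
#' diagnosis series reaches `stability_months`; everything else (including
#' too-early converters and reverters) is `other`.
#'
#' @param record A `subject_record` with at least one diagnosis.
#' @param conversion_month Month of the qualifying first AD diagnosis.
#' @param stability_months Required stability horizon for the stable groups.
#' @return One of `"converter"`, `"stable_NL"`, `"stable_MCI"`, `"other"`.
#' @export
classify_trajectory <- function(record, conversion_month = 36,
                                stability_months = 72) {
  dx <- record$diagnoses
  if (nrow(dx) == 0L)
    stop("record has no diagnoses", call. = FALSE)
  ad_months <- dx$month[dx$dx == "AD"]
  if (length(ad_months)) {
    if (min(ad_months) == conversion_month) return("converter")
    return("other")
  }
  horizon <- dx[dx$month <= stability_months, , drop = FALSE]
  if (nrow(horizon) && max(dx$month) >= stability_months) {
    if (all(horizon$dx == "NL")) return("stable_NL")
    if (all(horizon$dx == "MCI")) return("stable_MCI")
  }
  "other"
}

#' Age-match each case to one NL and one MCI control
#'
#' Greedy 1:1:1 matching without replacement.  Cases are processed in
#' ascending id order; for each, the nearest-age eligible candidate in each
#' pool (|age difference| <= `age_tolerance`) is chosen, ties broken by the
#' smaller id.  A case lacking an eligible partner in either pool is
#' dropped (with a logged reason) and consumes no controls.
#'
#' @param cases,pool_nl,pool_mci Named lists of `subject_record` objects.
#' @param age_tolerance Maximum |age difference| in years.
#' @return A list of class `matched_triples`; each element has fields
#'   `ad`, `nl`, `mci` (subject ids).  Dropped case ids and reasons are in
#'   `attr(, "dropped")`.
#' @export
match_controls <- function(cases, pool_nl, pool_mci, age_tolerance = 5) {
  get_ages <- function(pool) vapply(pool, function(r) r$age, numeric(1))
  case_ids <- sort(names(cases))
  nl_ids <- names(pool_nl); mci_ids <- names(pool_mci)
  nl_ages <- get_ages(pool_nl); mci_ages <- get_ages(pool_mci)
  nl_free <- rep(TRUE, length(nl_ids)); mci_free <- rep(TRUE, length(mci_ids))
  pick <- function(ages, ids, free, age) {
    d <- abs(ages - age)
    elig <- which(free & d <= age_tolerance)
    if (!length(elig)) return(NA_integer_)
    elig[order(d[elig], ids[elig])][1L]
  }
  triples <- list()
  dropped <- character(0)
  for (cid in case_ids) {
    age <- cases[[cid]]$age
    i_nl <- pick(nl_ages, nl_ids, nl_free, age)
    i_mci <- pick(mci_ages, mci_ids, mci_free, age)
    if (is.na(i_nl) || is.na(i_mci)) {
      miss <- c(if (is.na(i_nl)) "NL", if (is.na(i_mci)) "MCI")
      dropped[cid] <- sprintf("no eligible %s control within %g years",
                              paste(miss, collapse = "/"), age_tolerance)
      message(sprintf("match_controls: dropping case %s (%s)", cid, dropped[cid]))
      next
    }
    nl_free[i_nl] <- FALSE
    mci_free[i_mci] <- FALSE
    triples[[length(triples) + 1L]] <-
      list(ad = cid, nl = nl_ids[i_nl], mci = mci_ids[i_mci])
  }
  structure(triples, class = "matched_triples", dropped = dropped)
}

#' Assemble the matched training sets
#'
#' Labels every record by trajectory (first AD diagnosis at
#' `conversion_month`; NL/MCI stability through `stability_months`), keeps
#' subjects whose measurement window passes [extract_window()] (at least
#' `min_points` complete visits in `[start_month, end_month]`, endpoint
#' required), then age-matches each converter to one stable-NL and one
#' stable-MCI control via [match_controls()].
#'
#' @param records Named list of `subject_record` objects.
#' @param conversion_month,stability_months Passed to
#'   [classify_trajectory()].
#' @param start_month,end_month,min_points,require_endpoint Window filter;
#'   see [extract_window()].
#' @param age_tolerance Passed to [match_controls()].
#' @return A list with `triples` (a `matched_triples`), `groups` (named
#'   character vector for all records) and `window_rejections`.
#' @export
build_training_sets <- function(records, conversion_month = 36,
                                stability_months = 72,
                                start_month = 0, end_month = 24,
                                min_points = 4L, require_endpoint = TRUE,
                                age_tolerance = 5) {
  groups <- vapply(records, classify_trajectory,
                   character(1), conversion_month, stability_months)
  passes <- vapply(records, function(r)
    !is_rejected(extract_window(r, start_month, end_month,
                                min_points, require_endpoint)),
    logical(1))
  rejections <- names(records)[!passes]
  keep <- function(g) records[groups == g & passes]
  triples <- match_controls(keep("converter"), keep("stable_NL"),
                            keep("stable_MCI"), age_tolerance)
  list(triples = triples, groups = groups, window_rejections = rejections)
}

#' Assemble the (unmatched) test sets
#'
#' Test subjects are converters with a first AD diagnosis at
#' `conversion_month` (default 48) and stable NL/MCI subjects holding their
#' diagnosis for at least `stability_months` (default 84).  No age matching
#' is applied.  Each kept subject must pass the test window filter
#' (default: months `[12, 36]`, at least 3 complete visits, endpoint 36
#' required).  Any overlap with `train_ids` is a contract violation.
#'
#' @param records Named list of `subject_record` objects.
#' @param train_ids Character vector of training subject ids (must be
#'   disjoint from the selected test subjects).
#' @param conversion_month,stability_months Trajectory filter.
#' @param start_month,end_month,min_points,require_endpoint Window filter.
#' @return A list with `records` (named list of kept records), `groups`
#'   (named character vector over kept records) and `window_rejections`.
#' @export
build_test_sets <- function(records, train_ids = character(0),
                            conversion_month = 48, stability_months = 84,
                            start_month = 12, end_month = 36,
                            min_points = 3L, require_endpoint = TRUE) {
  groups <- vapply(records, classify_trajectory,
                   character(1), conversion_month, stability_months)
  sel <- groups != "other"
  overlap <- intersect(names(records)[sel], train_ids)
  if (length(overlap))
    stop(sprintf("test subjects overlap the training set: %s",
                 paste(overlap, collapse = ", ")), call. = FALSE)
  kept <- list()
  rejections <- character(0)
  for (id in names(records)[sel]) {
    w <- extract_window(records[[id]], start_month, end_month,
                        min_points, require_endpoint)
    if (is_rejected(w)) rejections[id] <- w$reason else kept[[id]] <- records[[id]]
  }
  list(records = kept, groups = groups[names(kept)],
       window_rejections = rejections)
}
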