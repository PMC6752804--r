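# Feature construction: measurement window -> time-augmented path ->
# baseline volumes concatenated with (log-)signature terms.

VOLUME_CHANNELS <- c("Wholebrain", "Hippocampus", "Ventricles")

#' Scale raw MRI volumes to the analysis scale
#'
#' Raw FreeSurfer-style volumes in mm^3 are divided by fixed constants so
#' that typical adult values land on the descriptive scale used throughout
#' the analysis: whole brain / 1e6 (so ~1.0), hippocampus / 1e3 (~7),
#' ventricles / 1e3 (~30).
#'
#' @param wholebrain,hippocampus,ventricles Raw volumes in mm^3 (vectors of
#'   equal length); all must be positive and finite.
#' @return A data frame with columns `wholebrain`, `hippocampus`,
#'   `ventricles` in scaled units.
#' @export
scale_volumes <- function(wholebrain, hippocampus, ventricles) {
  v <- cbind(wholebrain, hippocampus, ventricles)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("volumes must be positive and finite", call. = FALSE)
  data.frame(wholebrain = wholebrain / 1e6,
             hippocampus = hippocampus / 1e3,
             ventricles = ventricles / 1e3)
}

window_rejection <- function(reason, subject_id = NA_character_) {
  structure(list(reason = reason, subject_id = subject_id),
            class = "window_rejection")
}

#' Test whether a window extraction was rejected
#' @param x Result of [extract_window()].
#' @return Logical.
#' @export
is_rejected <- function(x) inherits(x, "window_rejection")

#' @export
print.window_rejection <- function(x, ...) {
  cat(sprintf("<window_rejection> %s (%s)\n", x$subject_id, x$reason))
  invisible(x)
}

#' Extract a subject's measurement window as a path
#'
#' Selects the visits in `[start_month, end_month]` at which all three
#' volumes are present, scales them with [scale_volumes()], and returns the
#' resulting 3-channel path.  Visits missing any one volume are dropped
#' wholesale, since the signature needs simultaneous channels.  If fewer
#' than `min_points` complete visits remain, or the endpoint visit is
#' required but absent, a `window_rejection` (a typed outcome, not an
#' error) is returned instead; see [is_rejected()].
#'
#' @param record A `subject_record`.
#' @param start_month,end_month Window bounds in months (inclusive).
#' @param min_points Minimum number of complete visits required.
#' @param require_endpoint If `TRUE`, a visit at exactly `end_month` is
#'   required.
#' @return A [labeled_path()] with channels Wholebrain, Hippocampus,
#'   Ventricles (scaled units), or a `window_rejection`.
#' @export
extract_window <- function(record, start_month = 0, end_month = 24,
                           min_points = 4L, require_endpoint = TRUE) {
  if (!inherits(record, "subject_record"))
    stop("`record` must be a subject_record", call. = FALSE)
  m <- record$measurements
  keep <- m$month >= start_month & m$month <= end_month &
    is.finite(m$wholebrain) & is.finite(m$hippocampus) & is.finite(m$ventricles)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < min_points)
    return(window_rejection(
      sprintf("too few complete visits (%d < %d)", nrow(m), min_points),
      record$subject_id))
  if (require_endpoint && !any(m$month == end_month))
    return(window_rejection(
      sprintf("no visit at required endpoint month %g", end_month),
      record$subject_id))
  sv <- scale_volumes(m$wholebrain, m$hippocampus, m$ventricles)
  labeled_path(m$month,
               cbind(sv$wholebrain, sv$hippocampus, sv$ventricles),
               VOLUME_CHANNELS)
}

#' Append time as an extra path channel
#'
#' Adds the visit month (raw months, unscaled) as the last channel, named
#' `"Time"`, so that time-dependent interactions enter the signature.
#'
#' @param path A [labeled_path()].
#' @return A [labeled_path()] with one more channel.
#' @export
time_augment <- function(path) {
  if (!inherits(path, "labeled_path"))
    stop("`path` must be a labeled_path", call. = FALSE)
  labeled_path(path$times, cbind(path$values, path$times),
               c(path$channel_names, "Time"))
}

#' Build a subject's classification feature vector
#'
#' From a time-augmented 4-channel path (Wholebrain, Hippocampus,
#' Ventricles, Time), builds the feature vector used for classification:
#' the three scaled baseline volumes (suffix `_BL`), then the degree-2
#' (log-)signature terms with the constant dropped.  The level-1 terms are
#' reordered so that the time increment is entry 4 and the volume
#' increments are entries 5-7; second-level terms keep lexicographic
#' channel order.  Increment terms are named `"(Incr. X)"` (signature) or
#' `"[Incr. X]"` (log signature); area terms are named `"(A, B)"` /
#' `"[A, B]"`.
#'
#' @param path A time-augmented [labeled_path()] with channels exactly
#'   `Wholebrain, Hippocampus, Ventricles, Time` in that order.
#' @param representation `"signature"` (23 features) or `"log_signature"`
#'   (13 features).
#' @param subject_id Optional id carried along for bookkeeping.
#' @return An object of class `feature_vector` with fields `subject_id`,
#'   `names`, `values`, `representation`.
#' @export
build_feature_vector <- function(path,
                                 representation = c("signature", "log_signature"),
                                 subject_id = NA_character_) {
  representation <- match.arg(representation)
  if (!inherits(path, "labeled_path"))
    stop("`path` must be a labeled_path", call. = FALSE)
  nm <- path$channel_names
  if (length(nm) != 4L || !identical(nm, c(VOLUME_CHANNELS, "Time")))
    stop("`path` must have channels (Wholebrain, Hippocampus, Ventricles, Time) in order",
         call. = FALSE)
  base_vals <- path$values[1L, 1:3]
  base_names <- paste0(nm[1:3], "_BL")
  ord <- c(4L, 1L, 2L, 3L)  # time increment 4th, volume increments 5th-7th
  if (representation == "signature") {
    sig <- compute_signature(path, 2L)
    lvl1 <- sig$levels[[2L]]
    inc_names <- sprintf("(Incr. %s)", nm[ord])
    idx2 <- level_indices(4L, 2L)
    lvl2_names <- apply(idx2, 1L, function(ii)
      sprintf("(%s, %s)", nm[ii[1L]], nm[ii[2L]]))
    names <- c(base_names, inc_names, lvl2_names)
    values <- c(base_vals, lvl1[ord], sig$levels[[3L]])
  } else {
    ls <- compute_log_signature(path, 2L)
    inc_names <- sprintf("[Incr. %s]", nm[ord])
    area_names <- sprintf("[%s, %s]", nm[ls$pairs[, 1L]], nm[ls$pairs[, 2L]])
    names <- c(base_names, inc_names, area_names)
    values <- c(base_vals, unname(ls$increments)[ord], unname(ls$areas))
  }
  structure(
    list(subject_id = subject_id, names = names, values = unname(values),
         representation = representation),
    class = "feature_vector"
  )
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s (%s), %d features\n",
              x$subject_id, x$representation, length(x$names)))
  print(setNames(x$values, x$names))
  invisible(x)
}

#' Featurize a set of subject records into a design matrix
#'
#' Applies [extract_window()], [time_augment()] and
#' [build_feature_vector()] to each record; subjects whose window is
#' rejected are reported, not errors.
#'
#' @param records Named list of `subject_record` objects.
#' @param start_month,end_month,min_points,require_endpoint Passed to
#'   [extract_window()].
#' @param representation Passed to [build_feature_vector()].
#' @return A list with `x` (numeric matrix, one row per accepted subject,
#'   feature names as columns) and `rejected` (named character vector of
#'   rejection reasons).
#' @export
featurize_records <- function(records, start_month = 0, end_month = 24,
                              min_points = 4L, require_endpoint = TRUE,
                              representation = "signature") {
  rows <- list()
  rejected <- character(0)
  for (id in names(records)) {
    w <- extract_window(records[[id]], start_month, end_month,
                        min_points, require_endpoint)
    if (is_rejected(w)) {
      rejected[id] <- w$reason
      next
    }
    fv <- build_feature_vector(time_augment(w), representation, id)
    rows[[id]] <- setNames(fv$values, fv$names)
  }
  x <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), nrow = 0L, ncol = 0L)
  list(x = x, rejected = rejected)
}
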