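#' Construct a labelled multivariate path
#'
#' A `labeled_path` is an ordered, time-stamped multivariate trajectory:
#' the discrete samples of one subject's biomarker channels at their visit
#' months.  Signature computations interpret it as the piecewise-linear
#' interpolant of those samples.
#'
#' @param times Numeric vector of sample parameters (months), strictly
#'   increasing, at least one sample.
#' @param values Numeric matrix with one row per sample and one column per
#'   channel (a plain vector is treated as a single channel).  All values
#'   must be finite.
#' @param channel_names Optional character vector of channel labels; defaults
#'   to `X1, X2, ...`.
#'
#' @return An object of class `labeled_path` with fields `times`, `values`
#'   and `channel_names`.
#' @examples
#' p <- labeled_path(0:4, cbind(c(2, 4, 6, 8, 10), c(1, 2, 8, 9, 10)))
#' compute_signature(p, degree = 2)
#' @export
labeled_path <- function(times, values, channel_names = NULL) {
  times <- as.numeric(times)
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(times) < 1L)
    stop("a path needs at least one sample", call. = FALSE)
  if (nrow(values) != length(times))
    stop("`values` must have one row per entry of `times`", call. = FALSE)
  if (any(!is.finite(times)))
    stop("`times` must be finite", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("path values must be finite", call. = FALSE)
  if (is.null(channel_names)) channel_names <- paste0("X", seq_len(ncol(values)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != ncol(values))
    stop("`channel_names` must match the number of channels", call. = FALSE)
  colnames(values) <- channel_names
  structure(
    list(times = times, values = values, channel_names = channel_names),
    class = "labeled_path"
  )
}

#' @export
print.labeled_path <- function(x, ...) {
  cat(sprintf(
    "<labeled_path> %d sample(s), %d channel(s) [%s], t in [%g, %g]\n",
    length(x$times), ncol(x$values), paste(x$channel_names, collapse = ", "),
    x$times[1L], x$times[length(x$times)]
  ))
  invisible(x)
}

#' @export
dim.labeled_path <- function(x) dim(x$values)
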