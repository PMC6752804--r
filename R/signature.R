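# Truncated path signatures of piecewise-linear paths.
#
# A level-k block is stored as a dense numeric vector of length d^k in
# lexicographic multi-index order with the first index most significant:
# position of (i1, ..., ik) is 1 + sum_j (i_j - 1) * d^(k - j).  With that
# layout the truncated tensor product of two blocks is kronecker(a, b).

new_signature_tensor <- function(dim, degree, levels) {
  structure(list(dim = as.integer(dim), degree = as.integer(degree),
                 levels = levels),
            class = "signature_tensor")
}

# all multi-indexes of length k over 1..d, rows in storage order
level_indices <- function(d, k) {
  if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  grid <- expand.grid(rev(replicate(k, seq_len(d), simplify = FALSE)),
                      KEEP.OUT.ATTRS = FALSE)
  as.matrix(grid[, rev(seq_len(k)), drop = FALSE])
}

# storage position of multi-index (i1, ..., ik)
tensor_position <- function(idx, d) {
  k <- length(idx)
  1L + sum((idx - 1L) * d^(k - seq_len(k)))
}

#' Signature of a single linear segment
#'
#' The truncated tensor exponential of one straight segment: the level-k
#' coefficient at multi-index \eqn{(i_1,\dots,i_k)} is
#' \eqn{\prod_j \Delta_{i_j} / k!}.
#'
#' @param increment Numeric vector of channel increments over the segment.
#' @param degree Truncation level (positive integer).
#' @return A `signature_tensor`.
#' @examples
#' segment_signature(c(8, 9), degree = 2)
#' @export
segment_signature <- function(increment, degree) {
  increment <- as.numeric(increment)
  if (any(!is.finite(increment)))
    stop("segment increment must be finite", call. = FALSE)
  degree <- as.integer(degree)
  if (length(degree) != 1L || is.na(degree) || degree < 1L)
    stop("`degree` must be a positive integer", call. = FALSE)
  d <- length(increment)
  levels <- vector("list", degree + 1L)
  levels[[1L]] <- 1
  block <- 1
  for (k in seq_len(degree)) {
    block <- as.numeric(kronecker(block, increment))
    levels[[k + 1L]] <- block / factorial(k)
  }
  new_signature_tensor(d, degree, levels)
}

# identity element of the truncated tensor algebra (signature of a constant path)
identity_signature <- function(dim, degree) {
  levels <- c(list(1), lapply(seq_len(degree), function(k) numeric(dim^k)))
  new_signature_tensor(dim, degree, levels)
}

#' Concatenate two signatures (Chen's identity)
#'
#' The signature of the concatenation of two paths is the truncated tensor
#' product of their signatures: level k of the result is
#' \eqn{\sum_{p=0}^{k} a_p \otimes b_{k-p}}.  The operation is associative
#' with the constant-path signature as neutral element.
#'
#' @param a,b `signature_tensor` objects with equal `dim` and `degree`.
#' @return A `signature_tensor`.
#' @export
chen_concat <- function(a, b) {
  if (!inherits(a, "signature_tensor") || !inherits(b, "signature_tensor"))
    stop("`a` and `b` must be signature_tensor objects", call. = FALSE)
  if (a$dim != b$dim || a$degree != b$degree)
    stop("signatures must share dimension and degree", call. = FALSE)
  m <- a$degree
  levels <- vector("list", m + 1L)
  levels[[1L]] <- 1
  for (k in seq_len(m)) {
    acc <- numeric(a$dim^k)
    for (p in 0:k) {
      acc <- acc + as.numeric(kronecker(a$levels[[p + 1L]],
                                        b$levels[[k - p + 1L]]))
    }
    levels[[k + 1L]] <- acc
  }
  new_signature_tensor(a$dim, m, levels)
}

#' Truncated path signature of a sampled path
#'
#' Computes the iterated-integral signature of the piecewise-linear
#' interpolant of the samples, by folding single-segment signatures with
#' Chen's identity.  A single-sample path yields the identity signature
#' (level 0 equal to 1, all higher levels zero).
#'
#' @param path A [labeled_path()].
#' @param degree Truncation level (positive integer).
#' @return A `signature_tensor`.
#' @examples
#' p <- labeled_path(0:4, cbind(c(2, 4, 6, 8, 10), c(1, 2, 8, 9, 10)))
#' sig <- compute_signature(p, 2)
#' unlist(sig$levels)  # 1, 8, 9, 32, 31, 41, 40.5
#' @export
compute_signature <- function(path, degree) {
  if (!inherits(path, "labeled_path"))
    stop("`path` must be a labeled_path", call. = FALSE)
  degree <- as.integer(degree)
  if (length(degree) != 1L || is.na(degree) || degree < 1L)
    stop("`degree` must be a positive integer", call. = FALSE)
  d <- ncol(path$values)
  sig <- identity_signature(d, degree)
  n <- nrow(path$values)
  if (n < 2L) return(sig)
  for (s in seq_len(n - 1L)) {
    inc <- path$values[s + 1L, ] - path$values[s, ]
    sig <- chen_concat(sig, segment_signature(inc, degree))
  }
  sig
}

#' Degree-2 log signature of a sampled path
#'
#' The formal logarithm of the degree-2 signature: the level-1 channel
#' increments together with one antisymmetric area term per unordered
#' channel pair, \eqn{A_{ij} = (S^{(i,j)} - S^{(j,i)})/2} for \eqn{i < j}
#' (the Levy area: area below the chord minus area above it).
#'
#' @param path A [labeled_path()].
#' @param degree Must be 2; higher degrees are not supported.
#' @return An object of class `log_signature` with fields `increments`
#'   (length d), `areas` (length d(d-1)/2) and `pairs` (matrix of the
#'   corresponding index pairs i < j).
#' @examples
#' p <- labeled_path(0:4, cbind(c(2, 4, 6, 8, 10), c(1, 2, 8, 9, 10)))
#' compute_log_signature(p)  # increments 8, 9; area -5
#' @export
compute_log_signature <- function(path, degree = 2L) {
  if (!identical(as.integer(degree), 2L))
    stop("only degree 2 is supported for the log signature", call. = FALSE)
  sig <- compute_signature(path, 2L)
  d <- sig$dim
  increments <- sig$levels[[2L]]
  names(increments) <- path$channel_names
  if (d >= 2L) {
    pairs <- t(utils::combn(d, 2L))
  } else {
    pairs <- matrix(integer(0), ncol = 2L)
  }
  lvl2 <- sig$levels[[3L]]
  areas <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    areas[r] <- (lvl2[tensor_position(c(i, j), d)] -
                   lvl2[tensor_position(c(j, i), d)]) / 2
  }
  if (nrow(pairs)) {
    names(areas) <- sprintf("[%s, %s]", path$channel_names[pairs[, 1L]],
                            path$channel_names[pairs[, 2L]])
  }
  structure(
    list(degree = 2L, dim = d, increments = increments, areas = areas,
         pairs = pairs, channel_names = path$channel_names),
    class = "log_signature"
  )
}

#' Export signature coefficients as named features
#'
#' Renders the coefficients of a signature (or degree-2 log signature) as an
#' ordered name/value table.  Terms appear level by level, within each level
#' in lexicographic multi-index order; names are rendered as
#' `"(Hippocampus, Time)"`-style tuples.  The constant level-0 term is
#' excluded (it is colinear with a classifier intercept).
#'
#' @param sig A `signature_tensor` or `log_signature`.
#' @param channel_names Character vector naming the channels (length equal
#'   to the signature dimension).
#' @return A data frame with columns `name` and `value`.
#' @export
signature_to_named_features <- function(sig, channel_names) {
  UseMethod("signature_to_named_features")
}

#' @export
signature_to_named_features.signature_tensor <- function(sig, channel_names) {
  channel_names <- as.character(channel_names)
  if (length(channel_names) != sig$dim)
    stop("`channel_names` must have length equal to the signature dimension",
         call. = FALSE)
  names <- character(0)
  values <- numeric(0)
  for (k in seq_len(sig$degree)) {
    idx <- level_indices(sig$dim, k)
    nm <- apply(idx, 1L, function(ii)
      sprintf("(%s)", paste(channel_names[ii], collapse = ", ")))
    names <- c(names, nm)
    values <- c(values, sig$levels[[k + 1L]])
  }
  data.frame(name = names, value = values, stringsAsFactors = FALSE)
}

#' @export
signature_to_named_features.log_signature <- function(sig, channel_names) {
  channel_names <- as.character(channel_names)
  if (length(channel_names) != sig$dim)
    stop("`channel_names` must have length equal to the signature dimension",
         call. = FALSE)
  inc_names <- sprintf("(%s)", channel_names)
  area_names <- if (nrow(sig$pairs)) {
    sprintf("[%s, %s]", channel_names[sig$pairs[, 1L]],
            channel_names[sig$pairs[, 2L]])
  } else character(0)
  data.frame(
    name = c(inc_names, area_names),
    value = c(unname(sig$increments), unname(sig$areas)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.signature_tensor <- function(x, ...) {
  cat(sprintf("<signature_tensor> dim %d, degree %d\n", x$dim, x$degree))
  print(unlist(x$levels))
  invisible(x)
}

#' @export
print.log_signature <- function(x, ...) {
  cat(sprintf("<log_signature> dim %d, degree 2\n", x$dim))
  cat("increments:\n"); print(x$increments)
  cat("areas:\n"); print(x$areas)
  invisible(x)
}
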