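# L1-penalised logistic regression over a lambda grid, 10-fold
# cross-validated deviance, lambda selection (min and min+1SE), ROC
# thresholding and confusion-matrix evaluation.

as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  y <- as.numeric(y)
  if (any(!y %in% c(0, 1)))
    stop("`y` must be binary (0/1)", call. = FALSE)
  y
}

#' Fit the Lasso logistic coefficient path
#'
#' For each value of the penalty \eqn{\lambda}, minimises the mean binomial
#' negative log-likelihood plus \eqn{\lambda \sum_j |\beta_j|} with an
#' unpenalised intercept.  Features are standardised to zero mean / unit
#' (population) variance internally and coefficients are reported on the
#' original scale.  The path is warm-started along the descending grid,
#' which by default runs from \eqn{\lambda_{max}} (the smallest penalty
#' with an all-zero solution) down to \eqn{\lambda_{max}/1000} over 100
#' logarithmically spaced values.
#'
#' @param x Numeric feature matrix (no missing or non-finite entries).
#' @param y Binary outcome (0/1, logical, or 2-level factor); both classes
#'   must be present.
#' @param lambdas Optional descending penalty grid; computed from the data
#'   when `NULL`.
#' @param nlambda,lambda_min_ratio Grid size and ratio of smallest to
#'   largest lambda, used when `lambdas` is `NULL`.
#' @param tol,maxit Convergence tolerance and iteration cap of the solver.
#' @return An object of class `l1_logit_path` with fields `lambdas`, `a0`
#'   (intercepts), `beta` (p x nlambda matrix, original scale), `beta_std`
#'   (standardised scale), `df` (nonzero count per lambda), `x_center`,
#'   `x_scale`, `feature_names`.
#' @export
fit_l1_logistic_path <- function(x, y, lambdas = NULL, nlambda = 100L,
                                 lambda_min_ratio = 1e-3,
                                 tol = 1e-7, maxit = 100L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x)))
    stop("`x` contains missing or non-finite entries", call. = FALSE)
  y <- as_binary(y)
  if (length(y) != nrow(x))
    stop("`y` must have one entry per row of `x`", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("`y` must contain both classes", call. = FALSE)
  n <- nrow(x)
  mu <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2L, mu)^2))  # population sd, glmnet-style
  s_safe <- ifelse(s > 0, s, 1)
  xs <- sweep(sweep(x, 2L, mu), 2L, s_safe, "/")
  if (is.null(lambdas)) {
    lambda_max <- max(abs(crossprod(xs, y - mean(y)))) / n
    lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                       length.out = nlambda))
  } else {
    lambdas <- sort(as.numeric(lambdas), decreasing = TRUE)
  }
  fit <- lasso_logistic_path_cpp(xs, y, lambdas, tol, maxit, maxit, 1e4)
  if (any(fit$diverged == 1L))
    warning("coefficients diverged (quasi-separation) at small lambda; capped",
            call. = FALSE)
  beta_std <- fit$beta
  beta <- beta_std / s_safe
  a0 <- fit$b0 - as.numeric(crossprod(beta_std, mu / s_safe))
  rownames(beta) <- rownames(beta_std) <- colnames(x)
  structure(
    list(lambdas = lambdas, a0 = a0, beta = beta, beta_std = beta_std,
         df = colSums(beta_std != 0), diverged = fit$diverged == 1L,
         x_center = mu, x_scale = s_safe, feature_names = colnames(x)),
    class = "l1_logit_path"
  )
}

#' @export
print.l1_logit_path <- function(x, ...) {
  cat(sprintf("<l1_logit_path> %d features, %d lambdas in [%.3g, %.3g]\n",
              nrow(x$beta), length(x$lambdas),
              min(x$lambdas), max(x$lambdas)))
  invisible(x)
}

#' Predict from a fitted Lasso path
#'
#' @param object An `l1_logit_path`.
#' @param newx Feature matrix with the training columns (matched by name
#'   when dimnames are present).
#' @param index Column index into the lambda grid.
#' @param type `"response"` (probability) or `"link"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.l1_logit_path <- function(object, newx, index,
                                  type = c("response", "link"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  if (!is.null(colnames(newx)) && !is.null(object$feature_names)) {
    missing <- setdiff(object$feature_names, colnames(newx))
    if (length(missing))
      stop(sprintf("`newx` is missing feature column(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    newx <- newx[, object$feature_names, drop = FALSE]
  }
  eta <- drop(object$a0[index] + newx %*% object$beta[, index])
  if (type == "link") eta else 1 / (1 + exp(-eta))
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stratified_folds <- function(y, folds, seed) {
  assignment <- integer(length(y))
  with_preserved_seed(seed, {
    pos <- 0L
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      # continue the round-robin across classes so fold sizes stay balanced
      assignment[idx] <- ((pos + seq_along(idx) - 1L) %% folds) + 1L
      pos <- pos + length(idx)
    }
  })
  assignment
}

#' Cross-validated Lasso logistic regression
#'
#' Fits the full-data coefficient path, then estimates per-lambda held-out
#' binomial deviance by stratified k-fold cross-validation on a shared
#' lambda grid.  `lambda_min` minimises the mean CV deviance (largest
#' lambda on ties); `lambda_1se` is the largest lambda whose CV deviance is
#' within one standard error (SD of the fold means / sqrt(k)) of that
#' minimum — the one-standard-error rule, favouring sparser models.
#'
#' @param x,y As in [fit_l1_logistic_path()]; `n >= folds` required.
#' @param lambdas Optional shared grid; defaults to the full-data grid.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for the stratified fold assignment.  If a fold
#'   assignment leaves a training fold single-class, folds are redrawn once
#'   (seed + 1) and then it is an error.
#' @param maxit Iteration cap for the fold fits (an inexact proximal-Newton
#'   cap: with heavily collinear signature features the deep small-lambda
#'   tail of each fold path converges slowly, and the held-out deviance
#'   curve and selected lambdas are insensitive to the extra precision).
#' @param ... Passed to [fit_l1_logistic_path()].
#' @return An object of class `lasso_cv` with the full-data `fit`,
#'   `lambdas`, `cv_deviance`, `cv_se`, `fold_deviance` (lambda x fold),
#'   `lambda_min`, `lambda_1se`, `index_min`, `index_1se`,
#'   `fold_assignment` and `seed`.
#' @export
cross_validate <- function(x, y, lambdas = NULL, folds = 10L, seed = 1L,
                           maxit = 25L, ...) {
  x <- as.matrix(x)
  y <- as_binary(y)
  n <- nrow(x)
  if (n < folds)
    stop("need at least as many observations as folds", call. = FALSE)
  full <- fit_l1_logistic_path(x, y, lambdas = lambdas, maxit = maxit, ...)
  lambdas <- full$lambdas
  assignment <- stratified_folds(y, folds, seed)
  ok <- function(a) all(vapply(seq_len(folds), function(k)
    length(unique(y[a != k])) == 2L, logical(1)))
  if (!ok(assignment)) {
    assignment <- stratified_folds(y, folds, seed + 1L)
    if (!ok(assignment))
      stop("a cross-validation training fold lost a class", call. = FALSE)
  }
  fold_dev <- matrix(NA_real_, nrow = length(lambdas), ncol = folds)
  for (k in seq_len(folds)) {
    tr <- assignment != k
    fit_k <- fit_l1_logistic_path(x[tr, , drop = FALSE], y[tr],
                                  lambdas = lambdas, maxit = maxit, ...)
    p_k <- 1 / (1 + exp(-(rep(fit_k$a0, each = sum(!tr)) +
                            x[!tr, , drop = FALSE] %*% fit_k$beta)))
    fold_dev[, k] <- vapply(seq_along(lambdas), function(l)
      binomial_deviance(y[!tr], p_k[, l]), numeric(1))
  }
  cv_dev <- rowMeans(fold_dev)
  cv_se <- apply(fold_dev, 1L, sd) / sqrt(folds)
  index_min <- which.min(cv_dev)  # first index = largest lambda on ties
  thresh <- cv_dev[index_min] + cv_se[index_min]
  index_1se <- min(which(cv_dev <= thresh))
  structure(
    list(fit = full, lambdas = lambdas, cv_deviance = cv_dev, cv_se = cv_se,
         fold_deviance = fold_dev,
         lambda_min = lambdas[index_min], lambda_1se = lambdas[index_1se],
         index_min = index_min, index_1se = index_1se,
         fold_assignment = assignment, seed = seed,
         feature_names = full$feature_names),
    class = "lasso_cv"
  )
}

#' @export
print.lasso_cv <- function(x, ...) {
  cat(sprintf(
    "<lasso_cv> %d lambdas; lambda_min = %.4g (%d features), lambda_1se = %.4g (%d features)\n",
    length(x$lambdas), x$lambda_min, x$fit$df[x$index_min],
    x$lambda_1se, x$fit$df[x$index_1se]))
  invisible(x)
}

#' Features selected at a chosen penalty
#'
#' @param result A `lasso_cv` object.
#' @param which `"1se"` (default) or `"min"`.
#' @return A data frame with `name`, `coefficient` (original scale) and
#'   `standardized` (coefficient on the standardised feature scale), in
#'   decreasing |standardised coefficient| order.
#' @export
selected_features <- function(result, which = c("1se", "min")) {
  which <- match.arg(which)
  idx <- if (which == "1se") result$index_1se else result$index_min
  b <- result$fit$beta[, idx]
  b_std <- result$fit$beta_std[, idx]
  nz <- which(b_std != 0)
  nz <- nz[order(-abs(b_std[nz]))]
  data.frame(name = result$feature_names[nz],
             coefficient = unname(b[nz]),
             standardized = unname(b_std[nz]),
             stringsAsFactors = FALSE)
}

#' Choose a probability threshold from the training ROC
#'
#' Scans the midpoints between consecutive distinct scores and returns the
#' threshold maximising Youden's J (sensitivity + specificity - 1); ties go
#' to the smallest threshold.  Degenerate all-equal scores give 0.5 with a
#' warning, as do scores with no better-than-chance cut-point.
#'
#' @param scores Predicted probabilities (or any monotone scores).
#' @param labels Binary labels (1 = positive class).
#' @return A single threshold; predictions are positive when
#'   `score > threshold`.
#' @export
choose_threshold <- function(scores, labels) {
  labels <- as_binary(labels)
  if (length(unique(labels)) < 2L)
    stop("`labels` must contain both classes", call. = FALSE)
  u <- sort(unique(scores))
  if (length(u) < 2L) {
    warning("degenerate scores (all equal); returning threshold 0.5",
            call. = FALSE)
    return(0.5)
  }
  cand <- (u[-1L] + u[-length(u)]) / 2
  jstat <- vapply(cand, function(th) {
    pred <- scores > th
    mean(pred[labels == 1]) - mean(pred[labels == 0])
  }, numeric(1))
  best <- max(jstat)
  if (best <= 0)
    warning("scores discriminate no better than chance at any threshold",
            call. = FALSE)
  cand[which(jstat == best)[1L]]  # candidates ascending: smallest threshold
}

#' Construct a confusion matrix
#'
#' @param counts 2x2 matrix of counts, rows = actual, columns = predicted,
#'   positive class first in both.
#' @param labels Length-2 character vector, positive class first.
#' @return An object of class `confusion_matrix` with `counts`, `labels`,
#'   `per_class_accuracy` (diagonal over row totals) and
#'   `balanced_accuracy`.
#' @examples
#' confusion_matrix(matrix(c(9, 1, 1, 19), 2, byrow = TRUE),
#'                  labels = c("AD", "NL"))
#' @export
confusion_matrix <- function(counts, labels = c("AD", "NL")) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0))
    stop("`counts` must be a 2x2 matrix of non-negative counts",
         call. = FALSE)
  dimnames(counts) <- list(actual = labels, predicted = labels)
  acc <- diag(counts) / rowSums(counts)
  structure(
    list(counts = counts, labels = labels,
         per_class_accuracy = acc, balanced_accuracy = mean(acc)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("            Predicted\n")
  cat(sprintf("%18s %6s %6s %8s\n", x$labels[1L], x$labels[2L], "Total",
              "Accuracy"))
  for (i in 1:2) {
    cat(sprintf("Actual %-6s %5d %6d %6d %8.2f\n", x$labels[i],
                x$counts[i, 1L], x$counts[i, 2L], sum(x$counts[i, ]),
                x$per_class_accuracy[i]))
  }
  invisible(x)
}

#' Evaluate a fitted model on test data
#'
#' Refit-free evaluation: scores the test rows with the full-data
#' coefficients at `lambda_1se` (or `lambda_min`), thresholds them, and
#' tabulates the confusion matrix with per-class accuracy.
#'
#' @param model A `lasso_cv` object.
#' @param threshold Probability threshold (see [choose_threshold()]).
#' @param x_test Feature matrix; columns must align by name with the
#'   training features (a mismatch is an error naming the columns).
#' @param y_test Binary labels (1 = positive class).
#' @param labels Length-2 class names, positive first.
#' @param which `"1se"` (default) or `"min"`.
#' @return A `confusion_matrix`.
#' @export
evaluate <- function(model, threshold, x_test, y_test,
                     labels = c("AD", "NL"), which = c("1se", "min")) {
  which <- match.arg(which)
  if (!inherits(model, "lasso_cv"))
    stop("`model` must be a lasso_cv object", call. = FALSE)
  x_test <- as.matrix(x_test)
  if (is.null(colnames(x_test)))
    stop("`x_test` must have named columns", call. = FALSE)
  missing <- setdiff(model$feature_names, colnames(x_test))
  extra <- setdiff(colnames(x_test), model$feature_names)
  if (length(missing) || length(extra))
    stop(sprintf("feature columns do not align with training%s%s",
                 if (length(missing)) paste0("; missing: ",
                                             paste(missing, collapse = ", ")) else "",
                 if (length(extra)) paste0("; unexpected: ",
                                           paste(extra, collapse = ", ")) else ""),
         call. = FALSE)
  x_test <- x_test[, model$feature_names, drop = FALSE]
  idx <- if (which == "1se") model$index_1se else model$index_min
  scores <- predict(model$fit, x_test, idx, type = "response")
  y_test <- as_binary(y_test)
  pred <- as.integer(scores > threshold)
  counts <- matrix(c(sum(y_test == 1 & pred == 1), sum(y_test == 1 & pred == 0),
                     sum(y_test == 0 & pred == 1), sum(y_test == 0 & pred == 0)),
                   nrow = 2L, byrow = TRUE)
  confusion_matrix(counts, labels)
}
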