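sim_logit_data <- function(n = 200, p = 10, beta3 = 1.5, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rbinom(n, 1, 1 / (1 + exp(-(beta3 * x[, 3] - 0.5))))
  list(x = x, y = y)
}

test_that("the null end of the path is exact", {
  d <- sim_logit_data()
  fit <- fit_l1_logistic_path(d$x, d$y)
  expect_equal(fit$df[1], 0)
  expect_equal(fit$a0[1], log(mean(d$y) / (1 - mean(d$y))), tolerance = 1e-8)
  expect_error(fit_l1_logistic_path(d$x, rep(1, nrow(d$x))), "both classes")
  xb <- d$x; xb[1, 1] <- NA
  expect_error(fit_l1_logistic_path(xb, d$y), "non-finite")
})

test_that("the coefficient path matches an independent solver", {
  skip_if_not_installed("glmnet")
  d <- sim_logit_data()
  fit <- fit_l1_logistic_path(d$x, d$y)
  g <- glmnet::glmnet(d$x, d$y, family = "binomial", lambda = fit$lambdas,
                      standardize = TRUE, thresh = 1e-14, maxit = 1e7)
  bg <- as.matrix(glmnet::coef.glmnet(g))
  for (j in c(5L, 25L, 50L, 75L, 100L)) {
    expect_lt(max(abs(c(fit$a0[j] - bg[1, j], fit$beta[, j] - bg[-1, j]))),
              1e-5)
  }
})

test_that("separable data at vanishing lambda is capped with a warning", {
  x <- matrix(c(-1, 1), 2, 1, dimnames = list(NULL, "f1"))
  y <- c(0, 1)
  expect_warning(fit <- fit_l1_logistic_path(x, y, lambdas = c(0.1, 0)),
                 "capped|separation")
  expect_true(all(is.finite(fit$beta)))
})

test_that("cross-validation honours the 1SE rule and is reproducible", {
  d <- sim_logit_data(n = 80, p = 6)
  cv1 <- cross_validate(d$x, d$y, folds = 10, seed = 7)
  cv2 <- cross_validate(d$x, d$y, folds = 10, seed = 7)
  expect_identical(cv1$cv_deviance, cv2$cv_deviance)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)

  expect_gte(cv1$lambda_1se, cv1$lambda_min)
  expect_equal(cv1$cv_deviance[cv1$index_min], min(cv1$cv_deviance))
  expect_lte(cv1$cv_deviance[cv1$index_1se],
             cv1$cv_deviance[cv1$index_min] + cv1$cv_se[cv1$index_min])
  # sparser model at the larger penalty
  expect_lte(cv1$fit$df[cv1$index_1se], cv1$fit$df[cv1$index_min])

  # held-out deviance at the null end approximates the null deviance
  pbar <- mean(d$y)
  null_dev <- -2 * mean(d$y * log(pbar) + (1 - d$y) * log(1 - pbar))
  expect_equal(cv1$cv_deviance[1], null_dev, tolerance = 0.05)
})

test_that("stratified folds keep both classes in every training fold", {
  set.seed(1)
  x <- matrix(rnorm(42 * 23), 42, 23, dimnames = list(NULL, paste0("f", 1:23)))
  y <- rep(c(1, 0), each = 21)
  cv <- cross_validate(x, y, folds = 10, seed = 3)
  sizes <- table(cv$fold_assignment)
  expect_true(all(sizes >= 4 & sizes <= 5))
  for (k in 1:10) {
    expect_setequal(unique(y[cv$fold_assignment != k]), c(0, 1))
  }
})

test_that("selected features are ranked by standardised magnitude", {
  set.seed(9)
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(rnorm(100 * 6), 100, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- rbinom(100, 1, 1 / (1 + exp(-2 * x[, 2])))
    cv <- suppressWarnings(cross_validate(x, y, folds = 10, seed = s))
    sel <- selected_features(cv, "1se")
    if (nrow(sel) && sel$name[1] == "f2") hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # planted predictor ranked first in >= 95% of seeds

  d <- sim_logit_data(n = 60, p = 4)
  fit_null <- cross_validate(d$x, d$y, folds = 10, seed = 1)
  grid_only_max <- fit_null$lambdas[1]
  cv_big <- cross_validate(d$x, d$y, lambdas = c(grid_only_max * 2,
                                                 grid_only_max),
                           folds = 10, seed = 1)
  expect_equal(nrow(selected_features(cv_big, "1se")), 0L)
})

test_that("the ROC threshold maximises Youden's J", {
  expect_equal(choose_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.5)
  expect_warning(th <- choose_threshold(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)),
                 "degenerate")
  expect_equal(th, 0.5)

  set.seed(21)
  for (rep in 1:20) {
    scores <- runif(30)
    labels <- rbinom(30, 1, 0.5)
    th <- suppressWarnings(choose_threshold(scores, labels))
    jfun <- function(t) mean(scores[labels == 1] > t) -
      mean(scores[labels == 0] > t)
    grid <- sort(unique(c(scores - 1e-9, scores + 1e-9)))
    expect_gte(jfun(th) + 1e-12, max(vapply(grid, jfun, numeric(1))))
  }
})

test_that("evaluation tabulates the confusion matrix and checks columns", {
  cm <- confusion_matrix(matrix(c(9, 1, 1, 19), 2, byrow = TRUE),
                         labels = c("AD", "NL"))
  expect_equal(unname(cm$per_class_accuracy), c(0.90, 0.95))

  d <- sim_logit_data(n = 80, p = 4)
  cv <- cross_validate(d$x, d$y, folds = 10, seed = 2)
  th <- suppressWarnings(choose_threshold(
    predict(cv$fit, d$x, cv$index_1se), d$y))
  cm2 <- evaluate(cv, th, d$x, d$y)
  expect_equal(sum(cm2$counts), nrow(d$x))
  expect_equal(sum(cm2$counts[1, ]), sum(d$y))

  x_bad <- d$x[, -2]
  expect_error(evaluate(cv, th, x_bad, d$y), "f2")
})
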