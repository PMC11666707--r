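test_that("fully shrunk logistic fit predicts the training prevalence", {
  host <- random_profiles(8, 3, "host", seed = 1)
  phage <- random_profiles(5, 3, "phage", seed = 2)
  d <- build_design(host, phage, kind = "linear")
  set.seed(3)
  y <- rbinom(nrow(d$X), 1, 0.3)
  fit <- suppressWarnings(
    fit_lasso_logistic(d, y, penalty_grid = c(1e6, 5e5), seed = 1))
  expect_true(all(fit$coefficients == 0))
  p <- predict_poa(fit, d)$probability
  expect_equal(unname(p), rep(mean(y), length(y)), tolerance = 1e-6)
})

test_that("a separable single-feature signal is recovered with zero training error", {
  host <- random_profiles(8, 3, "host", seed = 4)
  phage <- random_profiles(5, 3, "phage", seed = 5)
  d <- build_design(host, phage, kind = "linear")
  y <- as.integer(d$X[, "h_m1"])  # label IS one host mutation's indicator
  fit <- fit_lasso_logistic(d, y, penalty_grid = c(0.01, 0.001), seed = 1)
  expect_gt(fit$coefficients[["h_m1"]], 0)
  expect_equal(classification_error(y, predict_poa(fit, d)$class), 0)
})

test_that("identical inputs and seed give identical fits", {
  host <- random_profiles(10, 4, "host", seed = 6)
  phage <- random_profiles(6, 4, "phage", seed = 7)
  d <- build_design(host, phage, kind = "linear")
  set.seed(8)
  y <- rbinom(nrow(d$X), 1, 0.5)
  f1 <- fit_lasso_logistic(d, y, seed = 99)
  f2 <- fit_lasso_logistic(d, y, seed = 99)
  expect_identical(f1$penalty, f2$penalty)
  expect_identical(f1$coefficients, f2$coefficients)
})

test_that("single-class labels are rejected as degenerate", {
  host <- random_profiles(4, 2, "host", seed = 9)
  phage <- random_profiles(3, 2, "phage", seed = 10)
  d <- build_design(host, phage, kind = "h")
  expect_error(fit_lasso_logistic(d, rep(1, nrow(d$X)), seed = 1),
               "single class")
  expect_error(fit_lasso_logistic(d, rbinom(nrow(d$X), 1, 0.5),
                                  penalty_grid = numeric(0), seed = 1),
               "empty penalty grid")
})

test_that("EFF fit at the fully shrunk limit is the training mean", {
  host <- random_profiles(6, 3, "host", seed = 11)
  phage <- random_profiles(5, 3, "phage", seed = 12)
  d <- build_design(host, phage, kind = "linear")
  set.seed(13)
  y <- rnorm(nrow(d$X), 2)
  fit <- fit_lasso_linear(d, y, penalty_grid = c(1e6, 5e5), seed = 1)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$gamma, mean(y), tolerance = 1e-8)
})

test_that("planted additive effects are recovered with correct signs", {
  host <- random_profiles(20, 3, "host", seed = 14)
  phage <- random_profiles(10, 3, "phage", seed = 15)
  d <- build_design(host, phage, kind = "linear")  # 200 pairs
  set.seed(16)
  y <- as.numeric(2 * d$X[, "h_m1"] - 1 * d$X[, "p_m2"]) +
    rnorm(nrow(d$X), 0, 0.05)
  fit <- fit_lasso_linear(d, y, seed = 1)
  expect_gt(fit$coefficients[["h_m1"]], 0)
  expect_lt(fit$coefficients[["p_m2"]], 0)
})

test_that("POA predictions are the inverse logit of the linear predictor", {
  host <- random_profiles(2, 2, "host", seed = 17)
  phage <- random_profiles(2, 2, "phage", seed = 18)
  d <- build_design(host, phage, kind = "h")
  zero <- hand_model("POA", "h", 0, alpha = setNames(c(0, 0), colnames(host$incidence)), M = 2)
  pr <- predict_poa(zero, d)
  expect_equal(pr$probability, rep(0.5, 4))
  expect_equal(pr$class, rep(1L, 4))  # >= threshold at exactly 0.5

  deep_neg <- hand_model("POA", "h", -50,
                         alpha = setNames(c(0, 0), colnames(host$incidence)), M = 2)
  expect_equal(predict_poa(deep_neg, d)$class, rep(0L, 4))

  # hand-computed inverse logits on 4 pairs
  m <- hand_model("POA", "h", 0.5,
                  alpha = setNames(c(1, -2), colnames(host$incidence)), M = 2)
  eta <- 0.5 + as.numeric(d$X %*% c(1, -2))
  expect_equal(predict_poa(m, d)$probability, 1 / (1 + exp(-eta)))
})

test_that("EFF predictions match brute-force dot products and are additive", {
  host <- random_profiles(6, 3, "host", seed = 19)
  phage <- random_profiles(5, 3, "phage", seed = 20)
  d <- build_design(host, phage, kind = "linear")
  m <- hand_model("EFF", "linear", 0.3,
                  alpha = setNames(c(0, 0, 0), colnames(host$incidence)),
                  alpha_tilde = setNames(c(0, 0, 0), colnames(phage$incidence)))
  expect_equal(predict_eff(m, d), rep(0.3, 30))

  set.seed(21)
  m2 <- hand_model("EFF", "linear", -0.7,
                   alpha = setNames(rnorm(3), colnames(host$incidence)),
                   alpha_tilde = setNames(rnorm(3), colnames(phage$incidence)))
  brute <- apply(as.matrix(d$X), 1, function(r) -0.7 + sum(r * m2$coefficients))
  expect_equal(predict_eff(m2, d), unname(brute), tolerance = 1e-12)

  # additive identity: host differences are phage-independent
  eta <- matrix(predict_eff(m2, d), 6, 5)  # column-major grid order
  diffs <- eta[1, ] - eta[2, ]
  expect_equal(diffs, rep(diffs[1], 5))
  expect_equal(predict_eff(m2, d, exponentiate = TRUE),
               exp(predict_eff(m2, d)))
})

test_that("null models encode prevalence and mean", {
  expect_equal(fit_null("POA", c(1, 1, 0, 0))$p_hat, 0.5)
  expect_equal(unique(predict_null(fit_null("EFF", c(0, 2, 4)), 5)), 2.0)
  expect_error(fit_null("POA", integer(0)), "empty")
  n1 <- fit_null("POA", c(1, 0, 0, 0, 1))
  expect_identical(predict_null(n1, 20, seed = 5),
                   predict_null(n1, 20, seed = 5))
})

test_that("error metrics are exact mismatch fractions and mean deviations", {
  expect_equal(classification_error(c(0, 1, 1, 0), c(0, 1, 0, 0)), 0.25)
  expect_equal(classification_error(c(1, 0), c(1, 0)), 0)
  expect_equal(classification_error(c(1, 0), c(0, 1)), 1)
  expect_error(classification_error(c(1, 0), c(1)), "equal length")
  expect_equal(mean_absolute_error(c(1, 2), c(1, 2)), 0)
  expect_equal(mean_absolute_error(c(0, 0), c(1, -1)), 1)
  expect_equal(mean_absolute_error(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
})

test_that("the number of active coefficients is monotone along the penalty path", {
  host <- random_profiles(15, 5, "host", seed = 22)
  phage <- random_profiles(10, 5, "phage", seed = 23)
  d <- build_design(host, phage, kind = "linear")
  set.seed(24)
  y <- rnorm(nrow(d$X), as.numeric(d$X %*% rnorm(10)))
  lambdas <- c(2, 0.5, 0.1, 0.02, 0.004)  # decreasing
  nz <- vapply(lambdas, function(l) suppressWarnings(
    sum(abs(fit_lasso_linear(d, y, penalty_grid = l, seed = 1)$coefficients) > 1e-8)),
    numeric(1))
  # active set grows (weakly) as the penalty relaxes
  expect_true(all(diff(nz) >= 0))
})

test_that("fitted models serialize to JSON with nonzero coefficients only", {
  host <- random_profiles(10, 3, "host", seed = 25)
  phage <- random_profiles(5, 3, "phage", seed = 26)
  d <- build_design(host, phage, kind = "linear")
  set.seed(27)
  y <- rnorm(nrow(d$X), as.numeric(d$X[, 1] * 2))
  fit <- fit_lasso_linear(d, y, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  js <- jsonlite::read_json(path)
  expect_identical(js$task, "EFF")
  expect_true(all(unlist(js$coefficients) != 0))
  expect_equal(js$penalty, fit$penalty)
})
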