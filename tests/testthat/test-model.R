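test_that("single-gene panel reduces to textbook regression", {
  toy <- make_toy_long(G = 1, n = 40, beta = c(wb = 0.7), rho = 0, seed = 21)
  fit <- fit_ctra_model(toy$long, "wb", structure = "cs",
                        standardize_predictors = FALSE, method = "ml")
  ols <- lm(toy$Y[1, ] ~ toy$x)
  expect_equal(unname(wald_t(fit, "wb")$b), unname(coef(ols)[2]),
               tolerance = 1e-7)
  # ML variance (residual SS / n) drives the model-based SE
  n <- 40
  s2_ml <- sum(residuals(ols)^2) / n
  se_ml <- sqrt(s2_ml / sum((toy$x - mean(toy$x))^2))
  expect_equal(unname(wald_t(fit, "wb")$se), se_ml, tolerance = 1e-6)
})

test_that("HCS fit matches the brute-force dense-likelihood oracle", {
  toy <- make_toy_long(G = 4, n = 30, beta = c(wb = -0.4), rho = 0.3, seed = 22)
  fit <- fit_ctra_model(toy$long, "wb", structure = "hcs",
                        standardize_predictors = FALSE, method = "ml")
  oracle <- oracle_fit_dense(toy$Y, toy$X, "hcs")
  expect_equal(fit$logLik, oracle$logLik, tolerance = 1e-5)
  expect_equal(unname(wald_t(fit, "wb")$b), unname(oracle$beta),
               tolerance = 1e-5)
})

test_that("unstructured fit matches the dense oracle and estimates Sigma", {
  toy <- make_toy_long(G = 3, n = 40, beta = c(wb = 0.5), rho = 0.4, seed = 23)
  fit <- fit_ctra_model(toy$long, "wb", structure = "un",
                        standardize_predictors = FALSE, method = "ml",
                        ridge = 0)
  oracle <- oracle_fit_dense(toy$Y, toy$X, "un")
  expect_equal(fit$logLik, oracle$logLik, tolerance = 1e-5)
  expect_equal(unname(wald_t(fit, "wb")$b), unname(oracle$beta),
               tolerance = 1e-4)
  expect_true(isSymmetric(fit$Sigma))
  expect_true(all(eigen(fit$Sigma, only.values = TRUE)$values > 0))
})

test_that("CS with balanced data reproduces composite-score OLS exactly", {
  toy <- make_toy_long(G = 5, n = 35, beta = c(wb = -0.6), rho = 0.2,
                       sigma = rep(1, 5), seed = 24)
  fit <- fit_ctra_model(toy$long, "wb", structure = "cs",
                        standardize_predictors = FALSE)
  comp <- colMeans(toy$Y)
  ols <- lm(comp ~ toy$x)
  expect_equal(unname(wald_t(fit, "wb")$b), unname(coef(ols)[2]),
               tolerance = 1e-10)
})

test_that("between-within df bookkeeping is n minus predictors minus 1", {
  toy <- make_toy_long(G = 3, n = 30, seed = 25)
  set.seed(125)
  toy$long$z1 <- rep(rnorm(30), each = 3)
  toy$long$z2 <- rep(rnorm(30), each = 3)
  fit <- fit_ctra_model(toy$long, c("wb", "z1", "z2"))
  expect_equal(fit$df, 30 - 3 - 1)
  expect_equal(wald_t(fit, "z1")$df, 26)
})

test_that("omnibus F of a single term equals t squared", {
  toy <- make_toy_long(G = 3, n = 40, seed = 26)
  set.seed(126)
  toy$long$z1 <- rep(rnorm(40), each = 3)
  fit <- fit_ctra_model(toy$long, c("wb", "z1"))
  w <- wald_t(fit, "wb")
  f <- omnibus_f(fit, "wb")
  expect_equal(f$F, w$t^2, tolerance = 1e-10)
  expect_equal(f$df1, 1)
  f2 <- omnibus_f(fit, c("wb", "z1"))
  expect_equal(f2$df1, 2)
  expect_equal(f2$df2, fit$df)
})

test_that("contrasts use the coefficient covariance and equal terms give t = 0", {
  toy <- make_toy_long(G = 3, n = 50, seed = 27)
  set.seed(127)
  toy$long$z1 <- rep(rnorm(50), each = 3)
  fit <- fit_ctra_model(toy$long, c("wb", "z1"))
  expect_equal(contrast_test(fit, "wb", "wb")$t, 0)
  ct <- contrast_test(fit, "wb", "z1")
  manual_se <- sqrt(fit$vcov["wb", "wb"] + fit$vcov["z1", "z1"] -
                      2 * fit$vcov["wb", "z1"])
  expect_equal(ct$se, manual_se)
  expect_equal(ct$t, (wald_t(fit, "wb")$b - wald_t(fit, "z1")$b) / manual_se)
  expect_equal(ct$df, fit$df)
})

test_that("contrast of equal true effects rejects at the nominal rate", {
  # both predictors carry the same true effect; the contrast is null
  set.seed(28)
  reject <- logical(150)
  for (r in seq_len(150)) {
    n <- 60; G <- 6
    x1 <- rnorm(n); x2 <- rnorm(n)
    M <- matrix(0.2, G, G); diag(M) <- 1
    E <- t(chol(M)) %*% matrix(rnorm(G * n), G, n)
    Y <- 0.3 * matrix(x1 + x2, G, n, byrow = TRUE) + E
    dimnames(Y) <- list(paste0("g", 1:G), paste0("s", 1:n))
    long <- data.frame(subject_id = rep(colnames(Y), each = G),
                       gene = rep(rownames(Y), n), value = as.vector(Y),
                       x1 = rep(x1, each = G), x2 = rep(x2, each = G))
    fit <- fit_ctra_model(long, c("x1", "x2"), n_starts = 1)
    reject[r] <- contrast_test(fit, "x1", "x2")$p < 0.05
  }
  expect_gt(mean(reject), 0.005)
  expect_lt(mean(reject), 0.12)
})

test_that("VIF follows its closed form and flags only above 10", {
  set.seed(29)
  X <- cbind(a = rnorm(200), b = rnorm(200))
  expect_equal(vif(X, "a"), 1, tolerance = 0.05)
  # exact closed form at r = .9 via constructed columns
  n <- 1000
  z1 <- rnorm(n); z2 <- rnorm(n)
  z1 <- (z1 - mean(z1)) / sd(z1); z2 <- residuals(lm(z2 ~ z1))
  z2 <- (z2 - mean(z2)) / sd(z2)
  b <- 0.9 * z1 + sqrt(1 - 0.81) * z2
  X2 <- cbind(a = z1, b = b)
  expect_equal(vif(X2, "b"), 1 / (1 - 0.81), tolerance = 1e-10)
  expect_equal(vif(X2, "b"), 5.263158, tolerance = 1e-6)
  expect_lt(vif(X2, "b"), 10)
  # single predictor: VIF is 1 by definition
  expect_equal(vif(X[, "a", drop = FALSE], "a"), 1)
})

test_that("percent-difference transform spans the -2SD..+2SD contrast", {
  expect_equal(percent_difference_effect(0), 0)
  expect_equal(percent_difference_effect(0.25), 100)
  expect_equal(percent_difference_effect(-0.25), -50)
  b <- c(-0.1, 0.05, 0.3)
  expect_equal(percent_difference_effect(b), 100 * (2^(4 * b) - 1))
})

test_that("unbalanced or deficient inputs are rejected", {
  toy <- make_toy_long(G = 3, n = 20, seed = 30)
  expect_error(fit_ctra_model(toy$long[-1, ], "wb"), "unbalanced")
  long_na <- toy$long
  long_na$wb[4] <- NA
  expect_error(fit_ctra_model(long_na, "wb"), "NA")
  expect_error(fit_ctra_model(toy$long, "nope"), "missing columns")
})

test_that("REML estimates agree with nlme::gls REML on a small panel", {
  skip_if_not_installed("nlme")
  set.seed(31)
  G <- 3; n <- 60
  x <- rnorm(n); z <- 0.5 * x + rnorm(n)
  M <- matrix(0.4, G, G); diag(M) <- 1
  E <- t(chol(M)) %*% matrix(rnorm(G * n), G, n)
  Y <- seq_len(G) + c(1.2, 0.8, 1.0) * E + matrix(0.4 * x, G, n, byrow = TRUE)
  dimnames(Y) <- list(paste0("g", 1:G), paste0("s", 1:n))
  long <- data.frame(subject_id = rep(colnames(Y), each = G),
                     gene = factor(rep(rownames(Y), n)),
                     value = as.vector(Y), x = rep(x, each = G),
                     z = rep(z, each = G))
  fit <- fit_ctra_model(long, c("x", "z"), standardize_predictors = FALSE,
                        method = "reml", adjust_vcov = FALSE)
  ref <- nlme::gls(value ~ gene + x + z, data = long, method = "REML",
                   correlation = nlme::corCompSymm(form = ~1 | subject_id),
                   weights = nlme::varIdent(form = ~1 | gene))
  tab <- summary(ref)$tTable
  expect_equal(unname(wald_t(fit, "x")$b), unname(tab["x", "Value"]),
               tolerance = 1e-6)
  expect_equal(unname(wald_t(fit, "x")$se), unname(tab["x", "Std.Error"]),
               tolerance = 1e-5)
  expect_equal(unname(wald_t(fit, "z")$se), unname(tab["z", "Std.Error"]),
               tolerance = 1e-5)
})
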