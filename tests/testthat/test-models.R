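test_that("Shapiro-Wilk wrapper behaves under the null and the alternative", {
  set.seed(8)
  expect_gt(normality_check(rnorm(5000))$p_value, 0.01)
  expect_lt(normality_check(rexp(200))$p_value, 0.01)
  expect_error(normality_check(c(1, 2)), "at least 3")
  expect_error(normality_check(rep(2, 50)), "constant")
})

test_that("univariate screen finds a planted slope and skips constants", {
  set.seed(12)
  n <- 300
  X <- data.frame(x = rnorm(n), z = rnorm(n), const = rep(1, n))
  y <- 2 * X$x + rnorm(n, 0, 0.01)
  expect_warning(scr <- univariate_screen(y, X), "constant predictor")
  expect_true("x" %in% scr$selected)
  expect_equal(scr$table$beta[scr$table$predictor == "x"], 2, tolerance = 0.01)
  expect_warning(univariate_screen(rep(1, n), X[1:2]), "degenerate")
})

test_that("null univariate slope p-values are uniform", {
  pv <- sapply(1:200, function(i) {
    set.seed(3000 + i)
    y <- rnorm(200)
    x <- data.frame(x = rnorm(200))
    univariate_screen(y, x)$table$p
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.001)
  expect_lt(mean(pv <= 0.05), 0.12)
})

test_that("backward elimination keeps active predictors and removes noise", {
  keep_all <- 0
  noise_removed <- 0
  for (i in 1:40) {
    set.seed(500 + i)
    n <- 200
    X <- data.frame(a = rnorm(n), b = rnorm(n), noise = rnorm(n))
    y <- 1.5 * X$a - 1 * X$b + rnorm(n, 0, 0.8)
    fin <- backward_eliminate(y, X)
    if (setequal(fin$retained, c("a", "b"))) keep_all <- keep_all + 1
    if (!"noise" %in% fin$retained) noise_removed <- noise_removed + 1
  }
  expect_gte(noise_removed / 40, 0.9)
  expect_gte(keep_all / 40, 0.8)
})

test_that("backward elimination fixed point, tie-break and collinearity error", {
  set.seed(3)
  n <- 100
  X <- data.frame(x = rnorm(n))
  y <- X$x + rnorm(n, 0, 0.3)
  fin <- backward_eliminate(y, X)
  expect_identical(fin$retained, "x")
  expect_lte(fin$adjusted_r2, fin$r_squared)

  X2 <- data.frame(u = rnorm(n))
  X2$v <- 2 * X2$u   # exact collinearity
  expect_error(backward_eliminate(y, X2), "collinear")

  # order independence: shuffled columns give the same final set
  set.seed(4)
  X3 <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y3 <- X3$a + rnorm(n, 0, 2)
  f1 <- backward_eliminate(y3, X3)
  f2 <- backward_eliminate(y3, X3[, c(3, 1, 2)])
  expect_setequal(f1$retained, f2$retained)
})

test_that("exact LMG equals the brute-force all-orderings average", {
  for (i in 1:10) {
    set.seed(700 + i)
    n <- 60
    z <- rnorm(n)
    X <- data.frame(a = z + rnorm(n), b = 0.5 * z + rnorm(n), c = rnorm(n))
    y <- X$a - X$b + 0.3 * X$c + rnorm(n)
    shares <- lmg_decomposition(y, X)
    oracle <- lmg_bruteforce(y, X)
    expect_equal(as.numeric(shares) / 100, unname(oracle), tolerance = 1e-10)
    full_r2 <- summary(lm(y ~ ., data = X))$r.squared
    expect_equal(sum(shares), 100 * full_r2, tolerance = 1e-8)
  }
})

test_that("LMG analytic properties: orthogonal shares and single predictor", {
  n <- 8000
  set.seed(31)
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- X$a + 2 * X$b + rnorm(n)
  shares <- lmg_decomposition(y, X)
  r2a <- summary(lm(y ~ a, data = X))$r.squared
  r2b <- summary(lm(y ~ b, data = X))$r.squared
  # near-orthogonal predictors: share ~ own univariate R^2
  expect_equal(unname(shares["a"]) / 100, r2a, tolerance = 0.01)
  expect_equal(unname(shares["b"]) / 100, r2b, tolerance = 0.01)
  s1 <- lmg_decomposition(y, X["a"])
  expect_equal(as.numeric(s1) / 100, r2a, tolerance = 1e-10)
  expect_error(lmg_decomposition(y, as.data.frame(matrix(rnorm(n * 13), n))),
               "12 predictors")
})

test_that("confounder check reports near-zero deltas for independent confounders", {
  set.seed(41)
  n <- 2000
  X <- data.frame(pred = rnorm(n), age = rnorm(n, 65, 8),
                  sex = rbinom(n, 1, 0.5), education_years = rnorm(n, 14, 3))
  y <- 0.8 * X$pred + rnorm(n)
  cc <- confound_check(y, X, "pred")
  expect_false(cc$confounded)
  expect_lt(abs(cc$delta) / cc$share_unadjusted, 0.1)
  # confounder identical to the predictor -> collinearity error
  X$age <- X$pred
  expect_error(confound_check(y, X, "pred"), "collinear")
})

test_that("planted-path predictors are flagged unconfounded in most seeds", {
  flags <- sapply(1:20, function(i) {
    set.seed(900 + i)
    n <- 400
    X <- data.frame(pred = rnorm(n), age = rnorm(n, 65, 8),
                    sex = rbinom(n, 1, 0.5), education_years = rnorm(n, 14, 3))
    y <- 0.7 * X$pred + rnorm(n, 0, 0.7)
    !confound_check(y, X, "pred")$confounded
  })
  expect_gte(mean(flags), 0.95)
})

test_that("ROC analysis matches hand-computable cases and its invariants", {
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # monotone-transform invariance
  r2 <- roc_analysis(exp(c(1, 2, 3, 4)), c(0, 0, 1, 1))
  expect_equal(r2$auc, r$auc)
  # complement identity AUC(m) + AUC(-m) = 1
  set.seed(55)
  m <- rnorm(200); lab <- rbinom(200, 1, 0.5)
  expect_equal(roc_analysis(m, lab)$auc + roc_analysis(-m, lab)$auc, 1)
  expect_error(roc_analysis(m, rep(1, 200)), "classes")
})

test_that("random-forest importances are seed-deterministic and rank a planted effect first", {
  set.seed(66)
  n <- 150
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  x4 = rnorm(n), x5 = rnorm(n), x6 = rnorm(n))
  y <- 2 * X$x1 + rnorm(n, 0, 0.5)
  imp1 <- rf_importance(y, X, n_trees = 300, seed = 9)
  imp2 <- rf_importance(y, X, n_trees = 300, seed = 9)
  expect_identical(imp1, imp2)
  expect_equal(imp1$predictor[which.max(imp1$mda)], "x1")
  expect_equal(imp1$predictor[which.max(imp1$mdgc)], "x1")
  expect_error(rf_importance(rep(1, n), X), "constant")
  expect_error(rf_importance(y[1:10], X[1:10, ]), "n >= 20")
})

test_that("permuted outcomes leave all MDA importances in a noise band near zero", {
  set.seed(67)
  n <- 120
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- sample(2 * X$x1 + rnorm(n, 0, 0.5))   # permuted: no association left
  imp <- rf_importance(y, X, n_trees = 400, seed = 10)
  expect_lt(max(abs(imp$mda)), 3)   # scaled importances ~ z-scores
})

test_that("the prognosis fit recovers a planted model and its methods work", {
  ch <- chain_fit(400, seed = 17)
  fit <- fit_prognosis(ch$X, ch$ci, seed = 2, n_trees = 200)
  expect_s3_class(fit, "prognosis_fit")
  expect_true(all(c("grmp_theta", "executive", "working_memory") %in%
                    fit$final$retained))
  expect_equal(sum(fit$lmg), 100 * fit$final$r_squared, tolerance = 1e-6)
  expect_true(all(fit$final$coefficients$p <= fit$alpha))
  expect_output(print(fit), "final model")
  expect_output(summary(fit), "Univariate screen")
  expect_true(length(coef(fit)) >= 2)
  expect_equal(length(predict(fit)), length(residuals(fit)))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit, which = "lmg"))
})
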