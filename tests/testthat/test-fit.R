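oral <- oral_cancer()

test_that("saturated closed form gives log cross-product ratios", {
  fit <- fit_saturated_from_table(oral)
  expect_equal(unname(coef(fit)[c("a1b0", "a0b1", "a1b1")]),
               log(c(160 / 54, 120 / 36, 4500 / 498)))
  expect_equal(unname(vcov(fit)["a1b1", "a1b1"]),
               1 / 3 + 1 / 20 + 1 / 225 + 1 / 166)
  expect_equal(unname(vcov(fit)["a1b0", "a0b1"]), 1 / 3 + 1 / 20)
  # symmetric PSD with non-negative diagonal
  expect_equal(vcov(fit), t(vcov(fit)))
  expect_true(all(diag(vcov(fit)) >= 0))
})

test_that("IRLS on expanded subjects matches the closed form", {
  fit_cf <- fit_saturated_from_table(oral)
  fit_ml <- fit_logistic_mle(expand_subjects(oral))
  expect_true(fit_ml$converged)
  expect_equal(coef(fit_ml), coef(fit_cf), tolerance = 1e-7)
  expect_equal(vcov(fit_ml), vcov(fit_cf), tolerance = 1e-4)
  expect_equal(fit_ml$log_likelihood, fit_cf$log_likelihood, tolerance = 1e-8)
  # and on random all-positive tables
  set.seed(12)
  for (i in 1:5) {
    tab <- random_table()
    f1 <- fit_saturated_from_table(tab)
    f2 <- fit_logistic_mle(expand_subjects(tab))
    expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
    expect_equal(vcov(f1), vcov(f2), tolerance = 1e-5)
  }
})

test_that("null table gives zero effects; zero cells are rejected", {
  tab <- addint_table(cases = c(30, 40, 50, 60), controls = c(30, 40, 50, 60))
  expect_equal(unname(coef(fit_saturated_from_table(tab))), rep(0, 4))
  bad <- addint_table(cases = c(0, 8, 6, 225), controls = c(20, 18, 12, 166))
  expect_error(fit_saturated_from_table(bad), "empty cells")
  expect_message(fit_saturated_from_table(bad, continuity_correction = TRUE),
                 "continuity")
})

test_that("confounder coefficients are estimated and marginalised", {
  set.seed(3)
  n <- 4000
  a <- rbinom(n, 1, 0.3)
  b <- rbinom(n, 1, 0.4)
  x <- rnorm(n)
  eta <- -1 + 0.6 * (a & !b) + 0.8 * (!a & b) + 1.6 * (a & b) + 0.5 * x
  d <- data.frame(outcome = rbinom(n, 1, plogis(eta)),
                  factor_a = a, factor_b = b, x1 = x)
  fit <- fit_logistic_mle(d)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["x1"]), 0.5, tolerance = 0.15)
  est <- delta_interval(fit, "reri")
  expect_true(est$lower < est$point && est$point < est$upper)
})

test_that("delta intervals reproduce the oral-cancer example at 2 d.p.", {
  fit <- fit_saturated_from_table(oral)
  r <- delta_interval(fit, "reri")
  a <- delta_interval(fit, "ap")
  s <- delta_interval(fit, "s")
  expect_equal(round(c(r$point, r$lower, r$upper), 2), c(3.74, -1.84, 9.32))
  expect_equal(round(c(a$point, a$lower, a$upper), 2), c(0.41, -0.07, 0.90))
  expect_equal(round(c(s$point, s$lower, s$upper), 2), c(1.87, 0.65, 5.42))
})

test_that("delta intervals are symmetric and widen with the level", {
  fit <- fit_saturated_from_table(oral)
  for (ms in c("reri", "ap")) {
    e <- delta_interval(fit, ms)
    expect_equal(e$upper - e$point, e$point - e$lower, tolerance = 1e-10)
  }
  s <- delta_interval(fit, "s")
  expect_equal(log(s$upper) - log(s$point), log(s$point) - log(s$lower),
               tolerance = 1e-10)
  widths <- vapply(c(0.90, 0.95, 0.99), function(lv) {
    e <- delta_interval(fit, "reri", level = lv)
    e$upper - e$lower
  }, 0)
  expect_true(all(diff(widths) > 0))
})

test_that("analytic delta gradients agree with finite differences", {
  set.seed(20)
  for (i in 1:20) {
    tab <- random_table()
    fit <- fit_saturated_from_table(tab)
    b <- unname(coef(fit)[c("a1b0", "a0b1", "a1b1")])
    sig <- unname(vcov(fit)[2:4, 2:4])
    for (ms in c("reri", "ap", "s")) {
      f <- switch(ms, reri = oracle_reri, ap = oracle_ap, s = oracle_lns)
      if (ms == "s" && (exp(b[3]) <= 1 || exp(b[1]) + exp(b[2]) <= 2)) next
      g <- fd_gradient(f, b)
      se_fd <- sqrt(drop(t(g) %*% sig %*% g))
      est <- delta_interval(fit, ms)
      se_pkg <- if (ms == "s") est$diagnostics$se_log else est$diagnostics$se
      expect_equal(se_pkg, se_fd, tolerance = 1e-6)
    }
  }
})

test_that("degenerate covariance collapses the interval to the point", {
  fit <- fit_saturated_from_table(oral)
  fit$vcov[] <- 0
  e <- delta_interval(fit, "reri")
  expect_equal(e$lower, e$point)
  expect_equal(e$upper, e$point)
})

test_that("S delta interval refuses an out-of-domain point estimate", {
  tab <- addint_table(cases = c(50, 20, 20, 40), controls = c(50, 50, 50, 50))
  fit <- fit_saturated_from_table(tab)  # OR10, OR01 < 1: S undefined
  expect_error(delta_interval(fit, "s"), "undefined")
})
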