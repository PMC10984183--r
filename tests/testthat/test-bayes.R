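test_that("log posterior matches direct computation", {
  one <- addint_table(cases = c(1, 0, 0, 0), controls = c(0, 0, 0, 0))
  expect_equal(log_posterior(rep(0, 4), one),
               log(0.5) + 4 * dnorm(0, 0, 10, log = TRUE))
  # brute-force product-form oracle on a 5-subject toy dataset
  d <- data.frame(outcome = c(1, 0, 1, 0, 1),
                  factor_a = c(0, 0, 1, 1, 1),
                  factor_b = c(0, 1, 0, 1, 1))
  brute <- function(theta) {
    cat_i <- 1 + d$factor_a + 2 * d$factor_b
    eta <- theta[1] + c(0, theta[2:4])[cat_i]
    h <- 1 / (1 + exp(-eta))
    log(prod(h^d$outcome * (1 - h)^(1 - d$outcome))) +
      sum(dnorm(theta, 0, 10, log = TRUE))
  }
  set.seed(2)
  t1 <- rnorm(4); t2 <- rnorm(4)
  expect_equal(log_posterior(t1, d) - log_posterior(t2, d),
               brute(t1) - brute(t2), tolerance = 1e-10)
})

test_that("with a flat prior the posterior mode is the MLE", {
  tab <- addint_table(cases = c(10, 15, 20, 30), controls = c(30, 20, 15, 10))
  fit <- fit_saturated_from_table(tab)
  opt <- optim(rep(0, 4), function(th) -log_posterior(th, tab, prior_sd = 1e6),
               method = "BFGS")
  expect_equal(opt$par, unname(coef(fit)), tolerance = 1e-4)
})

test_that("sampler is deterministic given the seed", {
  tab <- addint_table(cases = c(10, 15, 20, 30), controls = c(30, 20, 15, 10))
  p1 <- sample_posterior(tab, n_iter = 500, n_burnin = 100, seed = 4)
  p2 <- sample_posterior(tab, n_iter = 500, n_burnin = 100, seed = 4)
  expect_identical(p1$chains, p2$chains)
  expect_true(all(p1$acceptance_rate > 0 & p1$acceptance_rate < 1))
  expect_equal(nrow(p1$chains[[1]]), 400)
})

test_that("posterior means match the quadrature oracle", {
  tab <- addint_table(cases = c(6, 9, 11, 17), controls = c(14, 12, 9, 8))
  exact <- posterior_mean_oracle(tab)
  post <- sample_posterior(tab, n_iter = 30000, n_burnin = 5000, n_chains = 2,
                           seed = 77)
  pooled <- do.call(rbind, post$chains)
  for (j in 1:4) {
    draws <- pooled[, j]
    # batch-means Monte Carlo standard error
    nb <- 50
    bm <- colMeans(matrix(draws[1:(nb * (length(draws) %/% nb))],
                          ncol = nb))
    mcse <- sd(bm) / sqrt(nb)
    expect_lt(abs(mean(draws) - exact[j]), 3.5 * mcse + 0.005)
  }
})

test_that("psrf detects convergence and its absence", {
  set.seed(10)
  n <- 5000
  same <- lapply(1:3, function(i) matrix(rnorm(n), ncol = 1,
                                         dimnames = list(NULL, "b")))
  expect_lt(unname(psrf(same)["b"]), 1.01)
  ident <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "b"))
  expect_equal(unname(psrf(list(ident, ident))["b"]), sqrt((n - 1) / n))
  apart <- list(ident, ident + 10)
  expect_gt(unname(psrf(apart)["b"]), 1.1)
  expect_error(psrf(list(ident)), "2 chains")
  expect_error(psrf(list(ident, ident[1:10, , drop = FALSE])), "equal")
})

test_that("posterior measure summaries are order statistics of the draws", {
  post <- sample_posterior(oral_cancer(), n_iter = 4000, n_burnin = 1000,
                           seed = 12)
  pm <- posterior_measures(post)
  pooled <- do.call(rbind, post$chains)
  or <- exp(pooled[, c("a1b0", "a0b1", "a1b1")])
  # independent sort-based route
  rer <- sort(or[, 3] - or[, 1] - or[, 2] + 1)
  n <- length(rer)
  expect_equal(pm$reri$lower, rer[ceiling(0.025 * n)])
  expect_equal(pm$reri$upper, rer[ceiling(0.975 * n)])
  expect_equal(pm$reri$point, median(rer))
  expect_true(pm$reri$lower <= pm$reri$point & pm$reri$point <= pm$reri$upper)
})

test_that("a degenerate posterior sample gives zero-width intervals", {
  draw <- matrix(rep(c(-1, log(2), log(3), log(12)), each = 50), ncol = 4,
                 dimnames = list(NULL, c("(Intercept)", "a1b0", "a0b1",
                                         "a1b1")))
  fake <- structure(list(chains = list(draw), n_iter = 50L, n_burnin = 0L,
                         seeds = 1L, acceptance_rate = 0.5,
                         psrf = rep(NA_real_, 4)),
                    class = "addint_posterior")
  pm <- posterior_measures(fake)
  expect_equal(pm$reri$point, 12 - 2 - 3 + 1)
  expect_equal(pm$reri$lower, pm$reri$upper)
  expect_equal(pm$s$point, 11 / 3)
})

test_that("posterior medians track the MLE for diffuse priors", {
  scen <- builtin_scenarios()["A2", ]
  tab <- draw_sample(scen, n_cases = 400, n_controls = 400, seed = 60)
  fit <- fit_saturated_from_table(tab)
  post <- sample_posterior(tab, n_iter = 12000, n_burnin = 4000, seed = 61)
  pooled <- do.call(rbind, post$chains)
  for (nm in c("a1b0", "a0b1", "a1b1")) {
    se <- sqrt(vcov(fit)[nm, nm])
    expect_lt(abs(median(pooled[, nm]) - coef(fit)[nm]), 0.3 * se)
  }
})

test_that("recoding per draw is a no-op when all factors carry clear risk", {
  tab <- addint_table(cases = c(30, 300, 300, 900),
                      controls = c(300, 100, 100, 30))
  post <- sample_posterior(tab, n_iter = 4000, n_burnin = 1000, seed = 14)
  plain <- posterior_measures(post, recode = FALSE)
  rec <- posterior_measures(post, recode = TRUE)
  for (ms in c("reri", "ap", "s")) {
    expect_equal(rec[[ms]]$point, plain[[ms]]$point)
    expect_equal(rec[[ms]]$lower, plain[[ms]]$lower)
    expect_equal(rec[[ms]]$upper, plain[[ms]]$upper)
  }
})

test_that("per-draw recoding matches the scalar recode on each draw", {
  set.seed(33)
  B <- matrix(rnorm(300, 0, 1.5), ncol = 3)
  vec <- addint:::recode_draws(B)
  for (i in sample(nrow(B), 20)) {
    expect_equal(vec[i, ], recode_lowest_reference(B[i, ])$coef)
  }
})

test_that("unreliable S summaries are flagged", {
  # antagonism so strong that most draws leave S's domain
  draw <- cbind(rnorm(400, -2, 0.1), rnorm(400, -2, 0.1), rnorm(400, -3, 0.1))
  colnames(draw) <- c("a1b0", "a0b1", "a1b1")
  draw <- cbind(`(Intercept)` = rnorm(400), draw)
  fake <- structure(list(chains = list(draw), n_iter = 400L, n_burnin = 0L,
                         seeds = 1L, acceptance_rate = 0.5,
                         psrf = rep(NA_real_, 4)),
                    class = "addint_posterior")
  pm <- posterior_measures(fake)
  expect_true(pm$s$diagnostics$unreliable)
  expect_false(pm$reri$diagnostics$unreliable)
})
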