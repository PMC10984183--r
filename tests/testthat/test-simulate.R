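test_that("builtin scenario table is internally consistent", {
  sc <- builtin_scenarios()
  expect_equal(nrow(sc), 20)
  expect_equal(sc$id, paste0(rep(c("A", "B", "C", "D"), each = 5), 1:5))
  m <- measures_from_coef(log(as.matrix(sc[c("or10", "or01", "or11")])))
  expect_equal(sc$reri, m$reri)
  expect_equal(sc$ap, m$ap)
  # hand-checked values
  expect_equal(sc["B1", "s"], 14 / 5)
  expect_equal(sc["C3", c("reri", "ap", "s")],
               data.frame(reri = 0, ap = 0, s = 1, row.names = "C3"))
  expect_equal(unname(round(sc["D4", "reri"], 2)), -0.88)
})

test_that("samples are reproducible and match the design frequencies", {
  scen <- builtin_scenarios()["A1", ]
  t1 <- draw_sample(scen, seed = 100)
  t2 <- draw_sample(scen, seed = 100)
  expect_identical(t1, t2)
  expect_equal(sum(t1$cases), 300)
  expect_equal(sum(t1$controls), 300)
  # control exposure frequencies across many draws: multinomial oracle
  set.seed(8)
  n_rep <- 400
  tot <- numeric(4)
  for (i in 1:n_rep)
    tot <- tot + draw_sample(scen, seed = sample.int(1e8, 1))$controls
  p <- c(0.6, 0.1, 0.2, 0.1)
  se <- sqrt(p * (1 - p) * 300 / n_rep)
  expect_true(all(abs(tot / n_rep - 300 * p) < 3.5 * se))
})

test_that("the sampled exposure odds ratios converge to the scenario ORs", {
  scen <- builtin_scenarios()["A1", ]
  big <- draw_sample(scen, n_cases = 5e5, n_controls = 5e5, seed = 42)
  ca <- as.numeric(big$cases); co <- as.numeric(big$controls)
  or11 <- (ca[4] * co[1]) / (ca[1] * co[4])
  or10 <- (ca[2] * co[1]) / (ca[1] * co[2])
  expect_equal(or11, 20, tolerance = 0.03)
  expect_equal(or10, 5, tolerance = 0.03)
})

test_that("confounded design recovers gamma and the scenario ORs", {
  scen <- builtin_scenarios()["A3", ]
  d <- draw_sample(scen, n_cases = 20000, n_controls = 20000,
                   confounder = TRUE, seed = 9)
  expect_equal(sum(d$outcome), 20000)
  expect_named(d, c("outcome", "factor_a", "factor_b", "x1"))
  fit <- fit_logistic_mle(d)
  expect_equal(unname(coef(fit)["x1"]), 0.5, tolerance = 0.1)
  expect_equal(unname(coef(fit)["a1b1"]), log(8), tolerance = 0.1)
})

test_that("coverage bookkeeping partitions and ranks correctly", {
  sc <- builtin_scenarios()[c("A3", "A5"), ]
  rep_ct <- 30
  cov <- run_coverage_study(sc, methods = c("delta", "boot_percentile"),
                            reps = rep_ct, seed = 5, B = 200)
  expect_s3_class(cov, "addint_coverage")
  expect_equal(nrow(cov), 2 * 3 * 2)
  # partition identity, exact per cell
  expect_equal(cov$left + cov$cover + cov$right, rep(100, nrow(cov)))
  expect_true(all(cov$n_used + cov$n_failed == rep_ct))
  # ranks are a permutation (ties averaged) within scenario x measure
  for (sid in unique(cov$scenario)) {
    for (ms in unique(cov$measure)) {
      r <- cov$rank[cov$scenario == sid & cov$measure == ms]
      expect_equal(sum(r), sum(seq_along(r)))  # averaged-tie permutation
    }
  }
  # target range recomputed from the binomial SE at this rep count
  expect_equal(attr(cov, "target_range"),
               95 + c(-1, 1) * 1.96 * sqrt(0.95 * 0.05 / rep_ct) * 100)
})

test_that("replicate seeds make the study reproducible", {
  sc <- builtin_scenarios()["A3", ]
  c1 <- run_coverage_study(sc, methods = "delta", reps = 25, seed = 77)
  c2 <- run_coverage_study(sc, methods = "delta", reps = 25, seed = 77)
  expect_equal(as.data.frame(c1), as.data.frame(c2))
})

test_that("point-estimate medians sit near the truth across replicates", {
  sc <- builtin_scenarios()["A3", ]
  cov <- run_coverage_study(sc, methods = "delta", reps = 200, seed = 31)
  reri_row <- cov[cov$measure == "reri", ]
  expect_lt(abs(reri_row$estimate - reri_row$true), 0.6)
  s_row <- cov[cov$measure == "s", ]
  expect_lt(abs(s_row$estimate - s_row$true), 0.15)
})

test_that("sampling distributions show the documented shapes", {
  # strong synergy: S right-skewed (mean > median); no interaction: RERI
  # approximately symmetric about zero
  sc <- builtin_scenarios()
  set.seed(90)
  draw_points <- function(scen, n_rep) {
    out <- matrix(NA_real_, n_rep, 3)
    for (i in seq_len(n_rep)) {
      fit <- fit_saturated_from_table(
        draw_sample(scen, seed = sample.int(1e8, 1)))
      b <- coef(fit)[c("a1b0", "a0b1", "a1b1")]
      out[i, ] <- unlist(measures_from_coef(b)[c("reri", "ap", "s")])
    }
    out
  }
  a1 <- draw_points(sc["A1", ], 300)
  expect_gt(mean(a1[, 3], na.rm = TRUE), median(a1[, 3], na.rm = TRUE))
  a3 <- draw_points(sc["A3", ], 300)
  mcse <- sd(a3[, 1]) / sqrt(nrow(a3))
  expect_lt(abs(mean(a3[, 1])), 2.5 * mcse + 0.25)
})
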