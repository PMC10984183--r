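#' Built-in simulation scenarios
#'
#' The 20 odds-ratio scenarios used by the package's coverage study:
#' four (OR01, OR10) pairs (blocks A-D) crossed with five OR11 values
#' ranging from strong synergy to strong antagonism. Exposure proportions
#' are fixed at (0.6, 0.1, 0.2, 0.1) for (A0B0, A1B0, A0B1, A1B1) among the
#' source population (controls), and the default design is balanced with 300
#' cases and 300 controls.
#'
#' @return A data frame with columns `id`, `or01`, `or10`, `or11` and the
#'   implied true measures `reri`, `ap`, `s`.
#' @examples
#' builtin_scenarios()[c("id", "reri", "ap", "s")]
#' @export
builtin_scenarios <- function() {
  blocks <- data.frame(block = c("A", "B", "C", "D"),
                       or01 = c(4, 2, 4, 2),
                       or10 = c(5, 5, 2.5, 2.5))
  or11 <- list(A = c(20, 12, 8, 6, 4),
               B = c(15, 9, 6, 4.5, 3),
               C = c(13.75, 8.25, 5.5, 4.125, 2.75),
               D = c(8.75, 5.25, 3.5, 2.625, 1.75))
  out <- do.call(rbind, lapply(seq_len(4), function(i) {
    data.frame(id = paste0(blocks$block[i], 1:5),
               or01 = blocks$or01[i], or10 = blocks$or10[i],
               or11 = or11[[i]])
  }))
  m <- interaction_measures(out$or10, out$or01, out$or11)
  out$reri <- m$reri
  out$ap <- m$ap
  out$s <- m$s
  rownames(out) <- out$id
  out
}

# exposure-category probabilities among controls / the source population
scenario_exposure_props <- c(A0B0 = 0.6, A1B0 = 0.1, A0B1 = 0.2, A1B1 = 0.1)

#' Draw one case-control sample under a scenario
#'
#' Without a confounder, controls' joint exposure is drawn multinomially with
#' probabilities `q = (0.6, 0.1, 0.2, 0.1)` and cases' with `p_j` proportional
#' to `q_j * OR_j` (`OR_0 = 1`), so the population exposure odds ratios
#' between cases and controls equal the scenario ORs exactly. With a
#' confounder, a source cohort is generated with exposure `~ q` and an
#' independent standard-normal covariate X, disease assigned by the logistic
#' model with coefficient `gamma` on X and the intercept solved numerically
#' so the cohort's expected case fraction matches the design fraction; the
#' requested numbers of cases and controls are then sampled from the cohort.
#'
#' @param scenario One row of [builtin_scenarios()] (or any list with
#'   `or10`, `or01`, `or11`).
#' @param n_cases,n_controls Sample sizes (defaults 300/300, the balanced
#'   design; the unbalanced design uses 200/400).
#' @param confounder Include the covariate X (default `FALSE`).
#' @param gamma Logistic coefficient of X (default 0.5).
#' @param seed Integer seed; required.
#' @return Without confounder: an [addint_table()]. With confounder: a
#'   subject-level data frame with column `x1`.
#' @export
draw_sample <- function(scenario, n_cases = 300, n_controls = 300,
                        confounder = FALSE, gamma = 0.5, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  q <- unname(scenario_exposure_props)
  or <- c(1, scenario$or10, scenario$or01, scenario$or11)
  set.seed(seed)
  if (!confounder) {
    p_case <- q * or / sum(q * or)
    ca <- drop(stats::rmultinom(1, n_cases, p_case))
    co <- drop(stats::rmultinom(1, n_controls, q))
    return(addint_table(cases = ca, controls = co))
  }
  beta <- log(or[2:4])
  phi <- n_cases / (n_cases + n_controls)
  b0 <- solve_intercept(beta, q, gamma, phi)
  n_cohort <- 8 * (n_cases + n_controls)
  cat_idx <- sample.int(4, n_cohort, replace = TRUE, prob = q)
  x <- stats::rnorm(n_cohort)
  eta <- b0 + c(0, beta)[cat_idx] + gamma * x
  y <- stats::rbinom(n_cohort, 1, stats::plogis(eta))
  i_case <- which(y == 1)
  i_ctrl <- which(y == 0)
  if (length(i_case) < n_cases || length(i_ctrl) < n_controls)
    stop("cohort too small to supply the requested cases/controls",
         call. = FALSE)
  keep <- c(sample(i_case, n_cases), sample(i_ctrl, n_controls))
  data.frame(outcome = y[keep],
             factor_a = as.integer(cat_idx[keep] %in% c(2L, 4L)),
             factor_b = as.integer(cat_idx[keep] %in% c(3L, 4L)),
             x1 = x[keep])
}

# intercept such that E[P(case)] over exposure ~ q and X ~ N(0,1) equals phi
solve_intercept <- function(beta, q, gamma, phi) {
  expected_p <- function(b0) {
    etas <- b0 + c(0, beta)
    sum(vapply(etas, function(e) {
      stats::integrate(function(x) stats::plogis(e + gamma * x) *
                         stats::dnorm(x), -Inf, Inf)$value
    }, 0) * q)
  }
  stats::uniroot(function(b0) expected_p(b0) - phi, c(-30, 30))$root
}

#' Coverage study of the interval procedures
#'
#' For each scenario and replicate, draws a case-control sample, computes the
#' requested interval procedures for RERI, AP and S, and tallies coverage of
#' the true value, left miscoverage (lower limit above the truth), right
#' miscoverage (upper limit below the truth), the median point estimate, and
#' per-scenario deviation ranks of |coverage - 95|. A cell is "in target" if
#' its coverage lies within `95 +/- 1.96 * sqrt(0.95 * 0.05 / reps) * 100`
#' percentage points (93.6-96.4 at 1000 replicates).
#'
#' Replicate-level fit failures (e.g. an empty reference cell) are counted
#' and the replicate excluded for the affected method/measure rather than
#' aborting the run.
#'
#' @param scenarios Data frame of scenarios as from [builtin_scenarios()]
#'   (subset rows to restrict).
#' @param methods Subset of `"delta"`, `"boot_percentile"`, `"boot_basic"`,
#'   `"boot_normal"`, `"bayes"`.
#' @param reps Replicates per scenario.
#' @param level Nominal level (default 0.95).
#' @param seed Master integer seed. Per-replicate seeds are drawn once per
#'   scenario from `seed + scenario index`, so any replicate can be
#'   reproduced in isolation.
#' @param n_cases,n_controls,confounder,gamma Passed to [draw_sample()].
#' @param B Bootstrap resamples per replicate (default 1000).
#' @param bayes Sampler settings for [sample_posterior()]; coverage-study
#'   defaults are a single chain of 10000 iterations with 5000 burn-in.
#' @return An `addint_coverage` data frame: one row per (scenario, measure,
#'   method) with columns `true`, `estimate` (median point estimate),
#'   `left`, `cover`, `right` (percentages), `n_used`, `n_failed`,
#'   `in_target`, `deviation` and `rank`.
#' @export
run_coverage_study <- function(scenarios, methods = c("delta",
                                                      "boot_percentile",
                                                      "bayes"),
                               reps = 1000, level = 0.95, seed,
                               n_cases = 300, n_controls = 300,
                               confounder = FALSE, gamma = 0.5, B = 1000,
                               bayes = list(n_iter = 10000, n_burnin = 5000,
                                            n_chains = 1)) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(reps >= 1)
  all_methods <- c("delta", "boot_percentile", "boot_basic", "boot_normal",
                   "bayes")
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  measures <- c("reri", "ap", "s")
  alpha <- 1 - level
  rows <- list()
  for (si in seq_len(nrow(scenarios))) {
    scen <- scenarios[si, ]
    set.seed(seed + si)
    rs <- matrix(sample.int(.Machine$integer.max - 1L, 3 * reps), ncol = 3)
    res <- array(NA_real_, c(reps, length(methods), length(measures), 3),
                 dimnames = list(NULL, methods, measures,
                                 c("point", "lower", "upper")))
    for (r in seq_len(reps)) {
      samp <- draw_sample(scen, n_cases, n_controls, confounder, gamma,
                          seed = rs[r, 1])
      fit <- tryCatch(
        if (inherits(samp, "addint_table")) fit_saturated_from_table(samp)
        else fit_logistic_mle(samp),
        error = function(e) NULL)
      if ("delta" %in% methods && !is.null(fit) && fit$converged) {
        for (ms in measures) {
          est <- tryCatch(delta_interval(fit, ms, level),
                          error = function(e) NULL)
          if (!is.null(est))
            res[r, "delta", ms, ] <- c(est$point, est$lower, est$upper)
        }
      }
      boot_methods <- sub("^boot_", "", grep("^boot_", methods, value = TRUE))
      if (length(boot_methods)) {
        ok <- tryCatch({
          bd <- bootstrap_draws(samp, B = B, seed = rs[r, 2])
          ints <- bootstrap_intervals(bd, boot_methods, level)
          for (nm in names(ints)) {
            est <- ints[[nm]]
            res[r, paste0("boot_", sub("^.*\\.", "", nm)), est$measure, ] <-
              c(est$point, est$lower, est$upper)
          }
          TRUE
        }, error = function(e) FALSE)
      }
      if ("bayes" %in% methods) {
        ok <- tryCatch({
          args <- utils::modifyList(list(x = samp, seed = rs[r, 3]), bayes)
          post <- do.call(sample_posterior, args)
          pm <- posterior_measures(post, level = level)
          for (ms in measures)
            res[r, "bayes", ms, ] <- c(pm[[ms]]$point, pm[[ms]]$lower,
                                       pm[[ms]]$upper)
          TRUE
        }, error = function(e) FALSE)
      }
    }
    truth <- c(reri = scen$reri, ap = scen$ap, s = scen$s)
    for (ms in measures) {
      for (mt in methods) {
        lo <- res[, mt, ms, "lower"]
        hi <- res[, mt, ms, "upper"]
        pt <- res[, mt, ms, "point"]
        used <- !is.na(lo) & !is.na(hi)
        tv <- truth[[ms]]
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = scen$id, measure = ms, method = mt, true = tv,
          estimate = stats::median(pt[used]),
          left = 100 * mean(lo[used] > tv),
          cover = 100 * mean(lo[used] <= tv & hi[used] >= tv),
          right = 100 * mean(hi[used] < tv),
          n_used = sum(used), n_failed = sum(!used))
      }
    }
  }
  out <- do.call(rbind, rows)
  half_width <- 1.96 * sqrt(level * (1 - level) / reps) * 100
  out$in_target <- abs(out$cover - 100 * level) <= half_width
  out$deviation <- abs(out$cover - 100 * level)
  out$rank <- stats::ave(out$deviation,
                         interaction(out$scenario, out$measure),
                         FUN = rank)
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  attr(out, "target_range") <- c(100 * level - half_width,
                                 100 * level + half_width)
  class(out) <- c("addint_coverage", "data.frame")
  out
}

#' @export
print.addint_coverage <- function(x, ...) {
  tr <- attr(x, "target_range")
  if (!is.null(tr))
    cat("Coverage study:", attr(x, "reps"), "replicates per scenario, ",
        sprintf("target range %.1f-%.1f%%\n", tr[1], tr[2]))
  d <- as.data.frame(x)
  for (nm in intersect(c("estimate", "left", "cover", "right", "deviation"),
                       names(d)))
    d[[nm]] <- round(d[[nm]], 2)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Run the oral-cancer worked example end to end
#'
#' Estimates the three measures on the packaged oral-cancer table with the
#' delta method, the percentile bootstrap (B = 1000) and the Bayesian sampler
#' at its defaults (N(0, 10^2) priors, 2 chains of 20000 iterations with
#' 10000 burn-in).
#'
#' @param seed Integer seed for the stochastic methods (default 2024).
#' @return The fitted `addint` object; `print()` it for the three-method
#'   report.
#' @export
run_example <- function(seed = 2024) {
  addint(oral_cancer(), methods = c("delta", "boot_percentile", "bayes"),
         B = 1000, seed = seed)
}
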