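#' Stratified resample of a case-control dataset
#'
#' Draws a bootstrap resample with replacement separately within cases and
#' within controls, so the resampled case and control counts always equal the
#' originals (the resampling design appropriate to case-control data, where
#' the two margins are fixed by design).
#'
#' @param data Subject-level data frame (`outcome`, `factor_a`, `factor_b`,
#'   optional confounders).
#' @return A data frame of the same shape and case/control composition.
#' @export
stratified_resample <- function(data) {
  check_subject_data(data)
  i_case <- which(data$outcome == 1)
  i_ctrl <- which(data$outcome == 0)
  if (!length(i_case) || !length(i_ctrl))
    stop("data must contain at least one case and one control", call. = FALSE)
  data[c(sample(i_case, length(i_case), replace = TRUE),
         sample(i_ctrl, length(i_ctrl), replace = TRUE)), , drop = FALSE]
}

#' Bootstrap distribution of the interaction measures
#'
#' Resamples the data `B` times (stratified within cases and controls),
#' refits each resample and records the RERI, AP and S draws. Without
#' confounders the stratified resample of subjects is equivalent to
#' multinomial resampling of the 2x4 cell counts, and the refit uses the
#' closed-form saturated estimator, so the whole distribution is computed
#' vectorised; with confounders each resample is refit by IRLS.
#'
#' Resamples with empty cells have no finite saturated MLE; for those draws
#' the refit falls back to IRLS, whose coefficients run toward the boundary
#' until the convergence criterion halts them, yielding very large odds
#' ratios. These extreme draws are retained in the order statistics -- this
#' is exactly what produces the enormous percentile upper limits seen with
#' sparse tables -- and their count is reported (`n_degenerate`). Draws at
#' which a measure is undefined (e.g. S outside its domain) are tagged `NA`
#' and excluded from that measure's order statistics, again with the
#' exclusion counted.
#'
#' @param x An [addint_table()] or subject-level data frame.
#' @param B Number of resamples (default 1000).
#' @param seed Integer seed; required, so that runs are reproducible.
#' @return An `addint_boot` object: list with `draws` (data frame of B rows,
#'   columns `reri`, `ap`, `s`), `point` (original-sample measures), `B`,
#'   `seed`, `n_failed` (IRLS non-convergences, confounder path only).
#' @examples
#' bootstrap_draws(oral_cancer(), B = 200, seed = 1)
#' @export
bootstrap_draws <- function(x, B = 1000, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(B >= 1)
  set.seed(seed)
  n_failed <- 0L
  n_degenerate <- 0L
  if (inherits(x, "addint_table") ||
      (is.data.frame(x) && !length(confounder_cols(x)))) {
    tab <- if (inherits(x, "addint_table")) x else collapse_subjects(x)
    ca <- as.numeric(tab$cases)
    co <- as.numeric(tab$controls)
    point <- interaction_measures((ca[2] * co[1]) / (ca[1] * co[2]),
                                  (ca[3] * co[1]) / (ca[1] * co[3]),
                                  (ca[4] * co[1]) / (ca[1] * co[4]))
    rca <- stats::rmultinom(B, sum(ca), ca / sum(ca))
    rco <- stats::rmultinom(B, sum(co), co / sum(co))
    degen <- colSums(rca == 0) + colSums(rco == 0) > 0
    n_degenerate <- sum(degen)
    or10 <- (rca[2, ] * rco[1, ]) / (rca[1, ] * rco[2, ])
    or01 <- (rca[3, ] * rco[1, ]) / (rca[1, ] * rco[3, ])
    or11 <- (rca[4, ] * rco[1, ]) / (rca[1, ] * rco[4, ])
    for (b in which(degen)) {    # no finite saturated MLE: IRLS fallback
      beta <- cell_glm_coef(rca[, b], rco[, b])
      or10[b] <- exp(beta[1]); or01[b] <- exp(beta[2]); or11[b] <- exp(beta[3])
    }
    draws <- data.frame(
      reri = or11 - or10 - or01 + 1,
      ap   = (or11 - or10 - or01 + 1) / or11,
      s    = ifelse(or11 > 1 & or10 + or01 > 2,
                    (or11 - 1) / (or10 + or01 - 2), NA_real_)
    )
    draws$reri[is.nan(draws$reri)] <- NA_real_
    draws$ap[is.nan(draws$ap)] <- NA_real_
    draws$s[is.nan(draws$s)] <- NA_real_
  } else {
    check_subject_data(x)
    fit0 <- fit_logistic_mle(x)
    cc <- category_coef(fit0)
    point <- measures_from_coef(cc$beta)
    draws <- matrix(NA_real_, B, 3)
    for (b in seq_len(B)) {
      res <- stratified_resample(x)
      fit <- tryCatch(suppressWarnings(fit_logistic_mle(res)),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        n_failed <- n_failed + 1L
        next
      }
      draws[b, ] <- unlist(measures_from_coef(category_coef(fit)$beta)[
        c("reri", "ap", "s")])
    }
    draws <- data.frame(reri = draws[, 1], ap = draws[, 2], s = draws[, 3])
  }
  structure(list(draws = draws, point = point, B = as.integer(B),
                 seed = as.integer(seed), n_failed = n_failed,
                 n_degenerate = n_degenerate),
            class = "addint_boot")
}

# IRLS fit of the saturated model from raw cell counts via a weighted
# binomial glm on the 8 (category, outcome) cells -- same likelihood as the
# subject-level fit, so identical coefficients, including the boundary-bound
# behaviour when cells are empty
cell_glm_coef <- function(ca, co) {
  d <- data.frame(y = rep(c(1, 0), each = 4),
                  a1b0 = rep(c(0, 1, 0, 0), 2),
                  a0b1 = rep(c(0, 0, 1, 0), 2),
                  a1b1 = rep(c(0, 0, 0, 1), 2),
                  w = c(ca, co))
  d <- d[d$w > 0, ]
  fit <- suppressWarnings(
    stats::glm(y ~ a1b0 + a0b1 + a1b1, data = d, family = stats::binomial(),
               weights = d$w,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  stats::coef(fit)[c("a1b0", "a0b1", "a1b1")]
}

#' @export
print.addint_boot <- function(x, ...) {
  cat("Bootstrap distribution: B =", x$B, "resamples, seed", x$seed, "\n")
  cat("undefined draws: reri", sum(is.na(x$draws$reri)),
      "| ap", sum(is.na(x$draws$ap)), "| s", sum(is.na(x$draws$s)),
      "| failed fits", x$n_failed, "\n")
  invisible(x)
}

# type-1 empirical quantile: order statistic at index ceiling(n * q)
quantile_type1 <- function(x, q) {
  x <- sort(x[!is.na(x)])        # sort() drops NA; Inf sorts last
  if (!length(x)) return(rep(NA_real_, length(q)))
  # the small slack keeps e.g. 1000 * 0.025 from rounding up to 26
  x[pmax(1L, ceiling(length(x) * q - 1e-9))]
}

#' Bootstrap confidence intervals for the interaction measures
#'
#' Builds percentile, basic and/or normal bootstrap intervals from a
#' bootstrap draw set. With `Z*_q` the type-1 empirical q-quantile of the
#' draws and `Zhat` the original-sample estimate:
#' percentile `(Z*_{a/2}, Z*_{1-a/2})`; basic
#' `(2 Zhat - Z*_{1-a/2}, 2 Zhat - Z*_{a/2})`; normal
#' `Zhat +/- z_{1-a/2} sd(draws)` (finite draws only).
#'
#' @param boot An `addint_boot` from [bootstrap_draws()].
#' @param methods Subset of `"percentile"`, `"basic"`, `"normal"`.
#' @param level Confidence level (default 0.95).
#' @return A list of `addint_estimate` objects, one per (measure, method),
#'   named `"<measure>.<method>"`. Diagnostics record the number of undefined
#'   draws excluded per measure.
#' @export
bootstrap_intervals <- function(boot,
                                methods = c("percentile", "basic", "normal"),
                                level = 0.95) {
  stopifnot(inherits(boot, "addint_boot"), level > 0, level < 1)
  methods <- match.arg(methods, several.ok = TRUE)
  alpha <- 1 - level
  z <- stats::qnorm(1 - alpha / 2)
  out <- list()
  for (measure in c("reri", "ap", "s")) {
    d <- boot$draws[[measure]]
    point <- boot$point[[measure]]
    n_undef <- sum(is.na(d))
    diag0 <- list(n_undefined = n_undef, n_failed = boot$n_failed, B = boot$B)
    qs <- quantile_type1(d, c(alpha / 2, 1 - alpha / 2))
    for (method in methods) {
      est <- switch(method,
        percentile = new_estimate(measure, point, qs[1], qs[2], level,
                                  "boot_percentile", diag0),
        basic = new_estimate(measure, point, 2 * point - qs[2],
                             2 * point - qs[1], level, "boot_basic", diag0),
        normal = {
          se <- stats::sd(d[is.finite(d)])
          new_estimate(measure, point, point - z * se, point + z * se, level,
                       "boot_normal",
                       c(diag0, list(se = se,
                                     n_infinite = sum(is.infinite(d)))))
        })
      out[[paste(measure, method, sep = ".")]] <- est
    }
  }
  out
}
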