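#' Estimate additive-scale interaction between two binary factors
#'
#' The central fitting function of the package. Fits the dummy-coded logistic
#' interaction model to a 2x4 case-control table, a subject-level data frame,
#' or a formula, and estimates the three additive-interaction measures
#' (RERI, AP, S) with intervals by one or more of: the delta method, the
#' stratified bootstrap (percentile / basic / normal constructions), and
#' Bayesian posterior sampling by random-walk Metropolis (equal-tailed
#' credible intervals).
#'
#' @param x An [addint_table()], a data frame with columns
#'   `outcome, factor_a, factor_b` plus optional numeric confounders, or a
#'   formula like `outcome ~ smoking + alcohol` or
#'   `outcome ~ smoking + alcohol + age` (first two right-hand terms are the
#'   binary factors, any further terms confounders).
#' @param methods Character vector from `"delta"`, `"boot_percentile"`,
#'   `"boot_basic"`, `"boot_normal"`, `"bayes"`.
#' @param level Confidence/credible level (default 0.95).
#' @param seed Integer seed; required when a bootstrap or Bayesian method is
#'   requested (there is no hidden default).
#' @param B Number of bootstrap resamples (default 1000).
#' @param recode Recode to the lowest-risk reference category before
#'   computing the measures (needed when a factor is preventive). Applied
#'   per posterior draw for the Bayesian method, and to the point fit for the
#'   frequentist methods.
#' @param bayes List of sampler settings passed to [sample_posterior()]:
#'   `n_iter` (20000), `n_burnin` (10000), `n_chains` (2), `prior_mean` (0),
#'   `prior_sd` (10), `tune` (2.38).
#' @param ... Passed between methods (e.g. `data` for the formula method).
#' @return An object of class `addint`: list with `fit` (the `addint_fit`),
#'   `estimates` (data frame with one row per measure x method), the raw
#'   `addint_estimate` objects in `$details`, and the bootstrap draws /
#'   posterior sample when those methods were run.
#' @examples
#' addint(oral_cancer())                                  # delta only
#' addint(oral_cancer(), methods = c("delta", "boot_percentile"),
#'        B = 200, seed = 7)
#' @export
addint <- function(x, ...) UseMethod("addint")

#' @rdname addint
#' @export
addint.addint_table <- function(x, methods = "delta", level = 0.95,
                                seed = NULL, B = 1000, recode = FALSE,
                                bayes = list(), ...) {
  addint_impl(x, expand_subjects(x), methods, level, seed, B, recode, bayes,
              match.call())
}

#' @rdname addint
#' @export
addint.data.frame <- function(x, methods = "delta", level = 0.95,
                              seed = NULL, B = 1000, recode = FALSE,
                              bayes = list(), ...) {
  check_subject_data(x)
  src <- if (length(confounder_cols(x))) x else collapse_subjects(x)
  addint_impl(src, x, methods, level, seed, B, recode, bayes, match.call())
}

#' @rdname addint
#' @param data Data frame holding the formula's variables (formula method).
#' @export
addint.formula <- function(x, data, ...) {
  vars <- all.vars(x)
  if (length(vars) < 3)
    stop("formula must name the outcome and two binary factors",
         call. = FALSE)
  d <- data.frame(outcome = as.integer(data[[vars[1]]]),
                  factor_a = as.integer(data[[vars[2]]]),
                  factor_b = as.integer(data[[vars[3]]]))
  for (nm in vars[-(1:3)]) d[[nm]] <- data[[nm]]
  addint.data.frame(d, ...)
}

addint_impl <- function(src, subjects, methods, level, seed, B, recode,
                        bayes, call) {
  all_methods <- c("delta", "boot_percentile", "boot_basic", "boot_normal",
                   "bayes")
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  needs_seed <- any(methods != "delta")
  if (needs_seed && is.null(seed))
    stop("'seed' is required for bootstrap and Bayesian methods",
         call. = FALSE)
  fit <- if (inherits(src, "addint_table")) fit_saturated_from_table(src)
         else fit_logistic_mle(src)
  details <- list()
  boot <- NULL
  posterior <- NULL

  if (recode) {
    rec <- recode_lowest_reference(category_coef(fit)$beta)
    if (rec$reference != "A0B0") {
      # refit on physically recoded factors so coefficients AND covariance
      # refer to the new reference (exact for the saturated model)
      subjects2 <- subjects
      if (rec$flip_a) subjects2$factor_a <- 1L - subjects2$factor_a
      if (rec$flip_b) subjects2$factor_b <- 1L - subjects2$factor_b
      src <- if (inherits(src, "addint_table")) collapse_subjects(subjects2)
             else subjects2
      subjects <- subjects2
      fit <- if (inherits(src, "addint_table")) fit_saturated_from_table(src)
             else fit_logistic_mle(src)
      attr(fit, "recoded") <- rec[c("reference", "flip_a", "flip_b")]
    }
  }

  if ("delta" %in% methods)
    for (measure in c("reri", "ap", "s"))
      details[[paste0(measure, ".delta")]] <-
        tryCatch(delta_interval(fit, measure, level), error = function(e) {
          warning(conditionMessage(e), call. = FALSE)
          NULL
        })

  boot_methods <- sub("^boot_", "", grep("^boot_", methods, value = TRUE))
  if (length(boot_methods)) {
    boot <- bootstrap_draws(src, B = B, seed = seed)
    details <- c(details, bootstrap_intervals(boot, boot_methods, level))
  }

  if ("bayes" %in% methods) {
    args <- utils::modifyList(
      list(x = src, seed = seed, n_iter = 20000, n_burnin = 10000,
           n_chains = 2, prior_mean = 0, prior_sd = 10, tune = 2.38),
      bayes)
    posterior <- do.call(sample_posterior, args)
    pm <- posterior_measures(posterior, recode = recode, level = level)
    names(pm) <- paste0(names(pm), ".bayes")
    details <- c(details, pm)
  }

  details <- Filter(Negate(is.null), details)
  estimates <- do.call(rbind, lapply(details, as.data.frame))
  rownames(estimates) <- NULL
  structure(list(fit = fit, estimates = estimates, details = details,
                 boot = boot, posterior = posterior, level = level,
                 recode = recode, call = call),
            class = "addint")
}

#' @export
print.addint <- function(x, digits = 2, ...) {
  cat("Additive-interaction estimates (",
      100 * x$level, "% intervals)\n\n", sep = "")
  e <- x$estimates
  fmt <- function(v) ifelse(is.finite(v) & abs(v) < 1e4,
                            sprintf("%.*f", digits, v),
                            formatC(v, format = "e", digits = 2))
  for (nm in c("point", "lower", "upper")) e[[nm]] <- fmt(e[[nm]])
  print(e[c("measure", "method", "point", "lower", "upper")],
        row.names = FALSE)
  rec <- attr(x$fit, "recoded")
  if (!is.null(rec))
    cat("\n(factors recoded: reference category moved to ", rec$reference,
        ")\n", sep = "")
  invisible(x)
}

#' @export
summary.addint <- function(object, ...) {
  cat("Call: ")
  print(object$call)
  print(object$fit)
  cat("\n")
  print(object)
  if (!is.null(object$boot)) print(object$boot)
  if (!is.null(object$posterior)) print(object$posterior)
  invisible(object)
}

#' @export
coef.addint <- function(object, ...) stats::coef(object$fit)

#' @export
vcov.addint <- function(object, ...) stats::vcov(object$fit)

#' @export
confint.addint <- function(object, parm = c("reri", "ap", "s"),
                           level = NULL, ...) {
  e <- object$estimates
  e[e$measure %in% parm, c("measure", "method", "lower", "upper")]
}

#' Histograms of the resampled / posterior measure distributions
#'
#' Draws one histogram per measure from the bootstrap draws or the posterior
#' sample (whichever the object holds; posterior preferred), with the point
#' estimate marked. Infinite and undefined draws are dropped from the
#' display; extreme tails are truncated at the 1% and 99% draw quantiles so
#' sparse-cell blowups do not flatten the picture.
#'
#' @param x An `addint` object fitted with a bootstrap or Bayesian method.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.addint <- function(x, ...) {
  draws <- if (!is.null(x$posterior)) {
    pooled <- do.call(rbind, x$posterior$chains)
    measures_from_coef(pooled[, c("a1b0", "a0b1", "a1b1")])
  } else if (!is.null(x$boot)) {
    x$boot$draws
  } else {
    stop("nothing to plot: refit with a bootstrap or Bayesian method",
         call. = FALSE)
  }
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  for (measure in c("reri", "ap", "s")) {
    d <- draws[[measure]]
    d <- d[is.finite(d)]
    q <- stats::quantile(d, c(0.01, 0.99))
    d <- d[d >= q[1] & d <= q[2]]
    graphics::hist(d, breaks = 40, main = toupper(measure), xlab = "",
                   col = "grey85", border = "grey40", ...)
    pt <- x$estimates$point[match(measure, x$estimates$measure)]
    graphics::abline(v = pt, col = "firebrick", lwd = 2)
  }
  invisible(x)
}
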