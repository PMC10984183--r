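#' Log posterior density of the logistic interaction model
#'
#' Log of (prior x Bernoulli likelihood) up to an additive constant, with
#' independent normal priors on every coefficient and
#' `h(x; theta) = 1 / (1 + exp(-linear predictor))`. Computed in log space
#' via `plogis(., log.p = TRUE)`, so it is stable for large |predictors|.
#'
#' @param theta Coefficient vector `(beta0, beta1, beta2, beta3, gamma...)`
#'   in dummy coding.
#' @param x An [addint_table()] (no confounders) or subject-level data frame.
#' @param prior_mean,prior_sd Normal prior mean and standard deviation,
#'   recycled across coefficients. Defaults 0 and 10 (diffuse).
#' @return The log posterior density (scalar).
#' @export
log_posterior <- function(theta, x, prior_mean = 0, prior_sd = 10) {
  make_log_posterior(x, prior_mean, prior_sd)(theta)
}

# closure factory: collapses a confounder-free input to cell counts so one
# evaluation costs O(4) instead of O(n)
make_log_posterior <- function(x, prior_mean = 0, prior_sd = 10) {
  stopifnot(all(prior_sd > 0))
  if (inherits(x, "addint_table") ||
      (is.data.frame(x) && !length(confounder_cols(x)))) {
    tab <- if (inherits(x, "addint_table")) x else collapse_subjects(x)
    ca <- as.numeric(tab$cases)
    co <- as.numeric(tab$controls)
    function(theta) {
      eta <- theta[1] + c(0, theta[2], theta[3], theta[4])
      sum(ca * stats::plogis(eta, log.p = TRUE) +
          co * stats::plogis(-eta, log.p = TRUE)) +
        sum(stats::dnorm(theta, prior_mean, prior_sd, log = TRUE))
    }
  } else {
    check_subject_data(x)
    X <- cbind(1,
               as.integer(x$factor_a == 1 & x$factor_b == 0),
               as.integer(x$factor_a == 0 & x$factor_b == 1),
               as.integer(x$factor_a == 1 & x$factor_b == 1),
               as.matrix(x[confounder_cols(x)]))
    y <- x$outcome
    function(theta) {
      eta <- drop(X %*% theta)
      sum(y * stats::plogis(eta, log.p = TRUE) +
          (1 - y) * stats::plogis(-eta, log.p = TRUE)) +
        sum(stats::dnorm(theta, prior_mean, prior_sd, log = TRUE))
    }
  }
}

#' Posterior sampling by random-walk Metropolis
#'
#' Samples the posterior of the logistic interaction-model coefficients with
#' Gaussian random-walk proposals accepted with probability
#' `min(1, exp(delta log posterior))`. The proposal covariance is the
#' classic optimal-scaling choice `(2.38^2 / d)` times the MLE covariance
#' (`d` = number of coefficients); if no MLE is available the identity is
#' used with a warning. Chain 1 starts at the MLE, later chains at the MLE
#' plus overdispersed normal jitter (2x the proposal sd).
#'
#' @inheritParams log_posterior
#' @param n_iter Total iterations per chain (default 20000).
#' @param n_burnin Burn-in iterations discarded per chain (default 10000).
#' @param n_chains Number of chains (default 2); potential scale reduction
#'   factors are reported when more than one chain is run.
#' @param seed Integer seed; required. Chain k uses `seed + k - 1`.
#' @param tune Scale factor of the random walk; proposal covariance is
#'   `(tune^2 / d) * Sigma_MLE`. Default 2.38.
#' @return An `addint_posterior`: list with `chains` (list of retained draw
#'   matrices, `n_iter - n_burnin` rows each, columns named like the fit
#'   coefficients), `n_iter`, `n_burnin`, `seeds`, `acceptance_rate` per
#'   chain, and `psrf` per parameter (NA with a single chain).
#' @examples
#' post <- sample_posterior(oral_cancer(), n_iter = 2000, n_burnin = 1000,
#'                          seed = 42)
#' @export
sample_posterior <- function(x, prior_mean = 0, prior_sd = 10,
                             n_iter = 20000, n_burnin = 10000, n_chains = 2,
                             seed, tune = 2.38) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(n_iter > n_burnin, n_burnin >= 0, n_chains >= 1)
  lp <- make_log_posterior(x, prior_mean, prior_sd)
  fit <- tryCatch({
    f <- if (inherits(x, "addint_table")) fit_saturated_from_table(x)
         else fit_logistic_mle(x)
    if (!f$converged) NULL else f
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("MLE unavailable for proposal tuning; using identity proposal ",
            "covariance")
    tab <- if (inherits(x, "addint_table")) x else NULL
    d <- if (!is.null(tab)) 4L
         else 4L + length(confounder_cols(x))
    sigma <- diag(d)
    start <- rep(0, d)
    par_names <- c("(Intercept)", "a1b0", "a0b1", "a1b1",
                   if (d > 4) paste0("g", seq_len(d - 4)))
  } else {
    sigma <- fit$vcov
    start <- unname(fit$coefficients)
    par_names <- names(fit$coefficients)
    d <- length(start)
  }
  prop_chol <- chol((tune^2 / d) * sigma)
  chains <- vector("list", n_chains)
  acc <- numeric(n_chains)
  seeds <- as.integer(seed + seq_len(n_chains) - 1L)
  for (k in seq_len(n_chains)) {
    set.seed(seeds[k])
    init <- start
    if (k > 1)
      init <- start + 2 * drop(stats::rnorm(d) %*% prop_chol)
    incr <- matrix(stats::rnorm(n_iter * d), n_iter, d) %*% prop_chol
    logu <- log(stats::runif(n_iter))
    draws <- matrix(NA_real_, n_iter, d, dimnames = list(NULL, par_names))
    cur <- init
    lp_cur <- lp(cur)
    n_acc <- 0L
    for (i in seq_len(n_iter)) {
      prop <- cur + incr[i, ]
      lp_prop <- lp(prop)
      if (logu[i] < lp_prop - lp_cur) {
        cur <- prop
        lp_cur <- lp_prop
        n_acc <- n_acc + 1L
      }
      draws[i, ] <- cur
    }
    chains[[k]] <- draws[(n_burnin + 1):n_iter, , drop = FALSE]
    acc[k] <- n_acc / n_iter
  }
  structure(list(chains = chains, n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), seeds = seeds,
                 acceptance_rate = acc,
                 psrf = if (n_chains > 1) psrf(chains)
                        else stats::setNames(rep(NA_real_, d), par_names)),
            class = "addint_posterior")
}

#' @export
print.addint_posterior <- function(x, ...) {
  cat("Posterior sample:", length(x$chains), "chain(s) x",
      nrow(x$chains[[1]]), "retained draws (", x$n_iter, "iterations,",
      x$n_burnin, "burn-in )\n")
  cat("acceptance rate:", paste(round(x$acceptance_rate, 3), collapse = ", "),
      "\n")
  if (!all(is.na(x$psrf)))
    cat("PSRF:", paste(sprintf("%s %.3f", names(x$psrf), x$psrf),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' For m >= 2 chains of length n, with W the mean within-chain variance and
#' B/n the between-chain variance of the chain means, returns
#' `sqrt(((n-1)/n * W + B/n) / W)` per parameter. Values near 1 indicate the
#' chains have mixed into the same distribution.
#'
#' @param chains List of draw matrices of equal dimensions (iterations x
#'   parameters).
#' @return Named numeric vector, one PSRF per parameter.
#' @export
psrf <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    stop("psrf needs >= 2 chains; for a single chain, split it in half ",
         "and pass the halves", call. = FALSE)
  n <- unique(vapply(chains, nrow, 1L))
  if (length(n) != 1) stop("chains must have equal lengths", call. = FALSE)
  m <- length(chains)
  means <- vapply(chains, colMeans, numeric(ncol(chains[[1]])))
  vars <- vapply(chains, function(ch) apply(ch, 2, stats::var),
                 numeric(ncol(chains[[1]])))
  means <- matrix(means, ncol = m)
  vars <- matrix(vars, ncol = m)
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  out <- sqrt(((n - 1) / n * W + B / n) / W)
  stats::setNames(out, colnames(chains[[1]]))
}

# vectorised per-draw recode to the lowest-risk reference; B is an n x 3
# matrix of (beta1, beta2, beta3) draws
recode_draws <- function(B) {
  full <- cbind(0, B)
  r <- max.col(-full, ties.method = "first")
  shifted <- full - full[cbind(seq_len(nrow(full)), r)]
  # slot j of the output = recoded category (A*1B*0, A*0B*1, A*1B*1);
  # perm[[r]] lists which original category (1..4) lands in each slot
  perm <- list(c(2L, 3L, 4L), c(1L, 4L, 3L), c(4L, 1L, 2L), c(3L, 2L, 1L))
  out <- matrix(NA_real_, nrow(B), 3)
  for (rr in 1:4) {
    idx <- r == rr
    if (any(idx)) out[idx, ] <- shifted[idx, perm[[rr]], drop = FALSE]
  }
  out
}

#' Posterior summaries of the interaction measures
#'
#' Maps every retained posterior draw through the measure formulas (after
#' per-draw recoding to the lowest-risk reference when `recode = TRUE`) and
#' summarises each measure by its posterior median and an equal-tailed
#' credible interval (the `alpha/2` and `1 - alpha/2` order statistics of the
#' mapped draws). Draws at which S is undefined are excluded from S's order
#' statistics, with the excluded fraction reported; if more than half the
#' draws are undefined the summary is flagged unreliable.
#'
#' @param sample An `addint_posterior` from [sample_posterior()].
#' @param recode Recode each draw to its lowest-risk reference category
#'   before computing the measures (for data with preventive factors).
#' @param level Credible level (default 0.95).
#' @param hpd If `TRUE`, report the highest-posterior-density (shortest)
#'   interval instead of the equal-tailed one.
#' @return A list of `addint_estimate` objects named `reri`, `ap`, `s`.
#'   Diagnostics carry the posterior mean, the undefined-draw fraction, and
#'   the `unreliable` flag.
#' @export
posterior_measures <- function(sample, recode = FALSE, level = 0.95,
                               hpd = FALSE) {
  stopifnot(inherits(sample, "addint_posterior"), level > 0, level < 1)
  pooled <- do.call(rbind, sample$chains)
  idx <- match(c("a1b0", "a0b1", "a1b1"), colnames(pooled))
  if (anyNA(idx)) stop("posterior sample lacks category coefficients",
                       call. = FALSE)
  B <- pooled[, idx, drop = FALSE]
  if (recode) B <- recode_draws(B)
  m <- measures_from_coef(B)
  alpha <- 1 - level
  method <- if (hpd) "bayes_hpd" else "bayes_equal_tail"
  out <- list()
  for (measure in c("reri", "ap", "s")) {
    d <- m[[measure]]
    n_undef <- sum(is.na(d))
    frac_undef <- n_undef / length(d)
    dd <- d[!is.na(d)]
    ci <- if (hpd) hpd_interval(dd, level)
          else quantile_type1(dd, c(alpha / 2, 1 - alpha / 2))
    out[[measure]] <- new_estimate(
      measure, stats::median(dd), ci[1], ci[2], level, method,
      diagnostics = list(mean = mean(dd), n_undefined = n_undef,
                         frac_undefined = frac_undef,
                         unreliable = frac_undef > 0.5,
                         n_draws = length(d)))
  }
  out
}

# shortest interval containing a `level` fraction of the sorted draws
hpd_interval <- function(x, level) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- max(1L, ceiling(level * n))
  if (k >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - k)
  widths <- x[starts + k] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + k])
}
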