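#' Delta-method confidence interval for an interaction measure
#'
#' Propagates the covariance of the category coefficients (beta1, beta2,
#' beta3) to the variance of RERI, AP or ln S by a first-order Taylor
#' approximation, giving a Wald-type interval `Z +/- z_{1-alpha/2} sqrt(g' S g)`
#' symmetric about the point estimate. For the synergy index the interval is
#' computed on the log scale and exponentiated, so it is symmetric about ln S.
#'
#' Gradients with respect to (beta1, beta2, beta3), writing
#' `OR_j = exp(beta_j)` and `D = OR10 + OR01 - 2`:
#' \itemize{
#'   \item RERI: `(-OR10, -OR01, OR11)`
#'   \item AP: `(-OR10/OR11, -OR01/OR11, (OR10 + OR01 - 1)/OR11)`
#'   \item ln S: `(-OR10/D, -OR01/D, OR11/(OR11 - 1))`
#' }
#'
#' @param fit An `addint_fit` from [fit_logistic_mle()] or
#'   [fit_saturated_from_table()].
#' @param measure One of `"reri"`, `"ap"`, `"s"`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return An `addint_estimate`: list with `measure`, `point`, `lower`,
#'   `upper`, `level`, `method = "delta"` and a `diagnostics` list carrying
#'   the standard error.
#' @examples
#' fit <- fit_saturated_from_table(oral_cancer())
#' delta_interval(fit, "reri")
#' @export
delta_interval <- function(fit, measure = c("reri", "ap", "s"), level = 0.95) {
  stopifnot(inherits(fit, "addint_fit"), level > 0, level < 1)
  measure <- match.arg(measure)
  if (!fit$converged)
    stop("fit did not converge; intervals would be unreliable", call. = FALSE)
  cc <- category_coef(fit)
  or <- exp(cc$beta)
  m <- interaction_measures(or[1], or[2], or[3])
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (measure == "s") {
    if (is.na(m$s))
      stop("synergy index undefined at the point estimate (",
           attr(synergy_index(or[1], or[2], or[3]), "reason"), ")",
           call. = FALSE)
    g <- c(-or[1], -or[2], 0) / (or[1] + or[2] - 2)
    g[3] <- or[3] / (or[3] - 1)
    se <- sqrt(drop(t(g) %*% cc$sigma %*% g))
    est <- new_estimate("s", m$s, exp(log(m$s) - z * se),
                        exp(log(m$s) + z * se), level, "delta",
                        diagnostics = list(se_log = se))
  } else {
    point <- if (measure == "reri") m$reri else m$ap
    g <- if (measure == "reri") c(-or[1], -or[2], or[3])
         else c(-or[1], -or[2], or[1] + or[2] - 1) / or[3]
    se <- sqrt(drop(t(g) %*% cc$sigma %*% g))
    est <- new_estimate(measure, point, point - z * se, point + z * se,
                        level, "delta", diagnostics = list(se = se))
  }
  est
}

new_estimate <- function(measure, point, lower, upper, level, method,
                         diagnostics = list()) {
  structure(list(measure = measure, point = point, lower = lower,
                 upper = upper, level = level, method = method,
                 diagnostics = diagnostics),
            class = "addint_estimate")
}

#' @export
print.addint_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("%s [%s]: %.*f (%.*f to %.*f), %g%% interval\n",
              toupper(x$measure), x$method, digits, x$point, digits, x$lower,
              digits, x$upper, 100 * x$level))
  invisible(x)
}

#' @export
as.data.frame.addint_estimate <- function(x, ...) {
  data.frame(measure = x$measure, method = x$method, point = x$point,
             lower = x$lower, upper = x$upper, level = x$level)
}
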