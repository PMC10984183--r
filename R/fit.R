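#' Maximum-likelihood logistic fit of the dummy-coded interaction model
#'
#' Fits `logit p = beta0 + beta1 I(A1B0) + beta2 I(A0B1) + beta3 I(A1B1) +
#' X gamma` by iteratively reweighted least squares (via [stats::glm()]),
#' with covariance taken as the inverse Fisher information at the MLE.
#'
#' @param data Data frame with binary `outcome`, `factor_a`, `factor_b` and
#'   optional numeric confounder columns.
#' @return An object of class `addint_fit`: list with `coefficients` (named
#'   `(Intercept)`, `a1b0`, `a0b1`, `a1b1`, then confounders), `vcov` (full
#'   covariance matrix), `log_likelihood`, `converged`, `n_iterations`, `n`,
#'   and `method = "irls"`.
#' @examples
#' fit_logistic_mle(expand_subjects(oral_cancer()))
#' @seealso [fit_saturated_from_table()] for the closed form on a 2x4 table.
#' @export
fit_logistic_mle <- function(data) {
  check_subject_data(data)
  if (length(unique(data$outcome)) < 2)
    stop("outcome must contain both cases and controls", call. = FALSE)
  conf <- confounder_cols(data)
  d <- data.frame(
    outcome = data$outcome,
    a1b0 = as.integer(data$factor_a == 1 & data$factor_b == 0),
    a0b1 = as.integer(data$factor_a == 0 & data$factor_b == 1),
    a1b1 = as.integer(data$factor_a == 1 & data$factor_b == 1)
  )
  for (nm in conf) d[[nm]] <- data[[nm]]
  if (nrow(d) < ncol(d))
    stop("fewer subjects than parameters", call. = FALSE)
  fit <- stats::glm(outcome ~ ., data = d, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  new_addint_fit(
    coefficients = stats::coef(fit),
    vcov = stats::vcov(fit),
    log_likelihood = as.numeric(stats::logLik(fit)),
    converged = fit$converged && !fit$boundary,
    n_iterations = fit$iter,
    n = nrow(d),
    method = "irls"
  )
}

#' Closed-form saturated fit from a 2x4 table
#'
#' For the saturated model with no confounders the MLE has a closed form:
#' `beta_j = ln[(cases_j * controls_0) / (cases_0 * controls_j)]` (log
#' cross-product ratios) with
#' `Var(beta_j) = 1/cases_j + 1/controls_j + 1/cases_0 + 1/controls_0` and
#' `Cov(beta_j, beta_k) = 1/cases_0 + 1/controls_0`. This equals the IRLS fit
#' on the expanded subject-level data.
#'
#' @param table An [addint_table()]; all 8 cells must be positive unless
#'   `continuity_correction` is set.
#' @param continuity_correction If `TRUE`, add 0.5 to every cell before
#'   fitting (off by default; a message notes when it is applied).
#' @return An `addint_fit` (see [fit_logistic_mle()]), `method = "saturated"`.
#' @examples
#' fit_saturated_from_table(oral_cancer())
#' @export
fit_saturated_from_table <- function(table, continuity_correction = FALSE) {
  stopifnot(inherits(table, "addint_table"))
  ca <- as.numeric(table$cases)
  co <- as.numeric(table$controls)
  if (any(ca == 0) || any(co == 0)) {
    if (!continuity_correction)
      stop("table has empty cells; set continuity_correction = TRUE ",
           "to add 0.5 to every cell", call. = FALSE)
    message("applying 0.5 continuity correction to all cells")
    ca <- ca + 0.5
    co <- co + 0.5
  }
  beta0 <- log(ca[1] / co[1])
  beta <- log((ca[2:4] * co[1]) / (ca[1] * co[2:4]))
  # inverse information of the saturated model: with cell weights
  # w_j = m_j p_j (1 - p_j) = cases_j * controls_j / m_j,
  # Var(b0) = 1/w_0, Var(b_j) = 1/w_j + 1/w_0, Cov(b_j, b_k) = 1/w_0,
  # Cov(b0, b_j) = -1/w_0, and 1/w_j = 1/cases_j + 1/controls_j.
  invw <- 1 / ca + 1 / co
  V <- matrix(invw[1], 4, 4)
  V[1, 2:4] <- V[2:4, 1] <- -invw[1]
  diag(V) <- c(invw[1], invw[2:4] + invw[1])
  nms <- c("(Intercept)", "a1b0", "a0b1", "a1b1")
  dimnames(V) <- list(nms, nms)
  p <- ca / (ca + co)
  ll <- sum(ca * log(p) + co * log(1 - p))
  new_addint_fit(
    coefficients = stats::setNames(c(beta0, beta), nms),
    vcov = V,
    log_likelihood = ll,
    converged = TRUE,
    n_iterations = 0L,
    n = sum(ca + co),
    method = "saturated"
  )
}

new_addint_fit <- function(coefficients, vcov, log_likelihood, converged,
                           n_iterations, n, method) {
  structure(list(coefficients = coefficients, vcov = vcov,
                 log_likelihood = log_likelihood, converged = converged,
                 n_iterations = n_iterations, n = n, method = method),
            class = "addint_fit")
}

#' @export
coef.addint_fit <- function(object, ...) object$coefficients

#' @export
vcov.addint_fit <- function(object, ...) object$vcov

#' @export
logLik.addint_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.addint_fit <- function(x, ...) {
  cat("Logistic interaction-model fit (", x$method, "), n = ", x$n,
      if (!x$converged) ", NOT converged" else "", "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

# the (beta1, beta2, beta3) coefficients and their covariance sub-block,
# confounders marginalised by taking the corresponding rows/columns of the
# full-model inverse information
category_coef <- function(fit) {
  idx <- match(c("a1b0", "a0b1", "a1b1"), names(fit$coefficients))
  list(beta = unname(fit$coefficients[idx]),
       sigma = unname(fit$vcov[idx, idx, drop = FALSE]))
}
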