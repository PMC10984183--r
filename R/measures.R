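#' Relative excess risk due to interaction (RERI)
#'
#' Computes RERI = RR11 - RR10 - RR01 + 1 from the three relative risks (or
#' odds ratios, under the rare-disease approximation) of the singly and doubly
#' exposed categories against the unexposed reference A0B0.
#'
#' RERI is zero under exact additivity of the two exposure effects on the
#' risk-difference scale, positive under synergy and negative under antagonism.
#'
#' @param rr10 Relative risk (or OR) of category A1B0 vs A0B0. Vectorised.
#' @param rr01 Relative risk (or OR) of category A0B1 vs A0B0.
#' @param rr11 Relative risk (or OR) of category A1B1 vs A0B0.
#' @return Numeric vector of RERI values.
#' @examples
#' reri(5, 4, 20)   # 12: strong synergy
#' reri(5, 4, 8)    # 0: exact additivity
#' @seealso [attributable_proportion()], [synergy_index()],
#'   [interaction_measures()]
#' @export
reri <- function(rr10, rr01, rr11) {
  check_rr(rr10, rr01, rr11)
  rr11 - rr10 - rr01 + 1
}

#' Attributable proportion due to interaction (AP)
#'
#' Computes AP = RERI / RR11, the fraction of the doubly exposed category's
#' relative risk attributable to interaction of the two factors.
#'
#' @inheritParams reri
#' @return Numeric vector of AP values.
#' @examples
#' attributable_proportion(5, 4, 20)      # 0.60
#' attributable_proportion(2.5, 2, 1.75)  # -1: strong antagonism
#' @export
attributable_proportion <- function(rr10, rr01, rr11) {
  check_rr(rr10, rr01, rr11)
  (rr11 - rr10 - rr01 + 1) / rr11
}

#' Synergy index (S)
#'
#' Computes S = (RR11 - 1) / (RR10 + RR01 - 2), the ratio of the joint excess
#' risk to the sum of the single-exposure excess risks. S equals 1 under
#' additivity, exceeds 1 under synergy and falls below 1 under antagonism; it
#' is only meaningful on (0, Inf), i.e. when both numerator and denominator
#' are strictly positive (both factors coded as risk factors).
#'
#' Outside that domain the function returns `NA` rather than raising, so that
#' resampled or posterior draws falling outside the domain can be counted and
#' reported instead of aborting a run. The reason for each undefined value is
#' available through the `"reason"` attribute.
#'
#' @inheritParams reri
#' @return Numeric vector; `NA` where S is undefined, with a character
#'   `"reason"` attribute ("" where defined) recording why.
#' @examples
#' synergy_index(5, 4, 20)  # 19/7 = 2.714...
#' synergy_index(5, 4, 8)   # 1: additivity
#' synergy_index(1, 1, 3)   # NA: zero denominator
#' @export
synergy_index <- function(rr10, rr01, rr11) {
  check_rr(rr10, rr01, rr11)
  num <- rr11 - 1
  den <- rr10 + rr01 - 2
  s <- num / den
  reason <- character(length(s))
  bad_num <- !is.na(num) & num <= 0
  bad_den <- !is.na(den) & den <= 0
  reason[bad_den] <- "rr10 + rr01 - 2 <= 0"
  reason[bad_num] <- ifelse(bad_den[bad_num],
                            "rr11 <= 1 and rr10 + rr01 - 2 <= 0", "rr11 <= 1")
  s[bad_num | bad_den] <- NA_real_
  attr(s, "reason") <- reason
  s
}

#' All three additive-interaction measures at once
#'
#' @inheritParams reri
#' @return A data frame with columns `reri`, `ap`, `s` and `ln_s` (one row per
#'   input triple). `s`/`ln_s` are `NA` where the synergy index is undefined
#'   (see [synergy_index()]).
#' @examples
#' interaction_measures(5, 4, 20)
#' @export
interaction_measures <- function(rr10, rr01, rr11) {
  s <- synergy_index(rr10, rr01, rr11)
  data.frame(
    reri = reri(rr10, rr01, rr11),
    ap   = attributable_proportion(rr10, rr01, rr11),
    s    = as.numeric(s),
    ln_s = log(as.numeric(s))
  )
}

check_rr <- function(rr10, rr01, rr11) {
  ok <- function(x) is.numeric(x) && all(is.na(x) | is.infinite(x) | x > 0)
  if (!ok(rr10) || !ok(rr01) || !ok(rr11))
    stop("relative risks / odds ratios must be strictly positive", call. = FALSE)
  invisible(NULL)
}

#' Interaction measures from logistic-regression coefficients
#'
#' Exponentiates the category coefficients of a dummy-coded logistic model
#' (`logit p = beta0 + beta1 I(A1B0) + beta2 I(A0B1) + beta3 I(A1B1)`) to the
#' odds-ratio triple and applies the three measure formulas. The product-term
#' parameterisation (`eta0 + eta1 A + eta2 B + eta3 AB`) is accepted and
#' converted to dummy coding first (`beta3 = eta1 + eta2 + eta3`); because
#' both models are saturated over the four exposure categories the two are
#' equivalent.
#'
#' @param coef Numeric vector (or 3-column matrix, one row per draw) holding
#'   the three non-reference category coefficients, in category order
#'   (A1B0, A0B1, A1B1) for `parameterization = "dummy"`, or (A, B, A:B) for
#'   `"product"`. Any intercept must be dropped by the caller.
#' @param parameterization `"dummy"` (default) or `"product"`.
#' @return A data frame as from [interaction_measures()].
#' @examples
#' measures_from_coef(log(c(5, 4, 20)))
#' measures_from_coef(log(c(5, 4, 1)), parameterization = "product")
#' @export
measures_from_coef <- function(coef, parameterization = c("dummy", "product")) {
  parameterization <- match.arg(parameterization)
  m <- if (is.matrix(coef)) coef else matrix(coef, nrow = 1)
  if (ncol(m) != 3)
    stop("'coef' must hold exactly 3 category coefficients", call. = FALSE)
  if (parameterization == "product")
    m[, 3] <- m[, 1] + m[, 2] + m[, 3]
  interaction_measures(exp(m[, 1]), exp(m[, 2]), exp(m[, 3]))
}

#' Recode to the lowest-risk reference category
#'
#' Additive-interaction measures are only meaningful when both factors are
#' risk factors, i.e. all non-reference categories carry risk at or above the
#' reference. When a preventive factor is present the exposure categories are
#' recoded so that the lowest-risk joint category becomes the reference:
#' resetting the reference is equivalent to subtracting the new reference
#' category's coefficient from all four category coefficients (the reference
#' coefficient being implicitly 0), so no refit is needed.
#'
#' Ties for the minimum prefer the original reference, then category order
#' A1B0, A0B1, A1B1, making the output deterministic.
#'
#' @param coef Numeric vector of the three dummy-coded category coefficients
#'   (A1B0, A0B1, A1B1); the A0B0 reference coefficient is implicitly 0.
#' @return A list with elements
#'   \item{coef}{recoded 3-vector, same category order expressed in the
#'     recoded factors (A*1B*0, A*0B*1, A*1B*1); all entries >= 0}
#'   \item{reference}{label of the original category now serving as reference}
#'   \item{flip_a, flip_b}{logicals: whether factor A (resp. B) was inverted,
#'     i.e. A* = 1 - A}
#' @examples
#' recode_lowest_reference(c(-0.5, 0.3, 0.7))  # reference moves to A1B0
#' recode_lowest_reference(c(0.2, 0.4, 0.9))   # identity: minimum already 0
#' @export
recode_lowest_reference <- function(coef) {
  stopifnot(is.numeric(coef), length(coef) == 3)
  cats <- c("A0B0", "A1B0", "A0B1", "A1B1")
  full <- c(0, coef)                      # coefficients of all four categories
  r <- which.min(full)                    # which.min takes the first of ties,
                                          # so A0B0 then category order wins
  shifted <- full - full[r]
  # exposure pattern (a, b) of each category, in `cats` order
  a <- c(0L, 1L, 0L, 1L)
  b <- c(0L, 0L, 1L, 1L)
  flip_a <- a[r] == 1L
  flip_b <- b[r] == 1L
  a_star <- if (flip_a) 1L - a else a
  b_star <- if (flip_b) 1L - b else b
  # reorder shifted coefficients so entry j is the category with recoded
  # pattern (a*, b*) = (1,0), (0,1), (1,1)
  key <- a_star * 1L + b_star * 2L        # 0 = reference, 1 = A*1B*0, ...
  out <- numeric(3)
  out[key[key > 0]] <- shifted[key > 0]
  list(coef = out, reference = cats[r], flip_a = flip_a, flip_b = flip_b)
}
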