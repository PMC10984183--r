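# Independent oracle routines used across the test files. These deliberately
# re-derive quantities by a different route than the package code.

# measure formulas written directly in terms of the coefficients
oracle_reri <- function(b) exp(b[3]) - exp(b[1]) - exp(b[2]) + 1
oracle_ap <- function(b) (exp(b[3]) - exp(b[1]) - exp(b[2]) + 1) / exp(b[3])
oracle_lns <- function(b) log(exp(b[3]) - 1) - log(exp(b[1]) + exp(b[2]) - 2)

# central finite-difference gradient
fd_gradient <- function(f, b, h = 1e-6) {
  vapply(seq_along(b), function(j) {
    e <- replace(numeric(length(b)), j, h)
    (f(b + e) - f(b - e)) / (2 * h)
  }, 0)
}

# random all-positive 2x4 table
random_table <- function() {
  addint_table(cases = sample(5:200, 4, replace = TRUE),
               controls = sample(5:200, 4, replace = TRUE))
}

# Exact posterior means of (beta0..beta3) for a 2x4 table under independent
# N(0, sd^2) priors, by quadrature over the per-category logits
# l = (b0, b0+b1, b0+b2, b0+b3). Given l0 the three remaining coordinates are
# conditionally independent, so everything reduces to 1-D grids.
posterior_mean_oracle <- function(tab, prior_sd = 10) {
  ca <- as.numeric(tab$cases)
  co <- as.numeric(tab$controls)
  m <- ca + co
  v2 <- 2 * prior_sd^2
  loglik <- function(l, j) ca[j] * l - m[j] * log1p(exp(l))
  l0g <- seq(-12, 12, length.out = 1601)
  lg <- seq(-12, 12, length.out = 1601)
  log_int <- matrix(0, length(l0g), 3)   # log of integral of g_j given l0
  cond_mean <- matrix(0, length(l0g), 3) # E[l_j | l0]
  for (j in 2:4) {
    llj <- loglik(lg, j)
    lw <- outer(l0g, lg, function(a, b) -(b - a)^2 / v2) +
      matrix(llj, length(l0g), length(lg), byrow = TRUE)
    mx <- apply(lw, 1, max)
    w <- exp(lw - mx)
    log_int[, j - 1] <- mx + log(rowSums(w))
    cond_mean[, j - 1] <- rowSums(w * matrix(lg, length(l0g), length(lg),
                                             byrow = TRUE)) / rowSums(w)
  }
  lp0 <- loglik(l0g, 1) - l0g^2 / v2 + rowSums(log_int)
  p0 <- exp(lp0 - max(lp0))
  p0 <- p0 / sum(p0)
  e_l0 <- sum(p0 * l0g)
  e_lj <- colSums(p0 * cond_mean)
  c(e_l0, e_lj - e_l0)  # (beta0, beta1, beta2, beta3)
}
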