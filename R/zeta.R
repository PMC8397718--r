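# Riemann zeta and its derivative.
#
# zeta(s) itself comes from pracma::zeta. The derivative zeta'(s) is not
# available there, so it is computed from the Euler-Maclaurin expansion
#
#   zeta(s) = sum_{n<M} n^-s + M^-s/2 + M^(1-s)/(s-1)
#             + sum_k B_{2k}/(2k)! * prod_{j=0}^{2k-2}(s+j) * M^(-s-2k+1)
#
# differentiated term by term in s. With M = 24 and Bernoulli terms up to
# B_12 the truncation error is far below double precision for s > 1.

.bernoulli2k <- c(1 / 6, -1 / 30, 1 / 42, -1 / 30, 5 / 66, -691 / 2730)

zeta_fun <- function(s) {
  if (s <= 1) stop("zeta(s) diverges for s <= 1", call. = FALSE)
  pracma::zeta(s)
}

zeta_deriv <- function(s, M = 24L) {
  if (s <= 1) stop("zeta'(s) requires s > 1", call. = FALSE)
  n <- seq_len(M - 1L)
  out <- -sum(log(n) * n^(-s))
  lM <- log(M)
  out <- out - lM * M^(-s) / 2
  out <- out - lM * M^(1 - s) / (s - 1) - M^(1 - s) / (s - 1)^2
  for (k in seq_along(.bernoulli2k)) {
    j <- 0:(2L * k - 2L)
    P <- prod(s + j)
    dP <- P * sum(1 / (s + j))
    ck <- .bernoulli2k[k] / factorial(2L * k)
    out <- out + ck * (dP - P * lM) * M^(-s - 2 * k + 1)
  }
  out
}

# Euler-Maclaurin zeta value; retained as an in-package cross-check of the
# same expansion the derivative uses.
zeta_em <- function(s, M = 24L) {
  n <- seq_len(M - 1L)
  out <- sum(n^(-s)) + M^(-s) / 2 + M^(1 - s) / (s - 1)
  for (k in seq_along(.bernoulli2k)) {
    j <- 0:(2L * k - 2L)
    out <- out + .bernoulli2k[k] / factorial(2L * k) * prod(s + j) *
      M^(-s - 2 * k + 1)
  }
  out
}
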