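# Independent BCa oracle, coded directly from the textbook formulas:
# z0 = Phi^-1(#{theta* < theta_hat}/B) (ties half-weighted, clamped to the
# achievable range), a = jackknife skewness, endpoints = interpolated order
# statistics of the bootstrap distribution at the adjusted levels.
bca_oracle <- function(boot, obs, jack, level) {
  B <- length(boot)
  u <- (sum(boot < obs) + 0.5 * sum(boot == obs)) / B
  u <- min(max(u, 1 / (B + 1)), B / (B + 1))
  z0 <- qnorm(u)
  th <- mean(jack) - jack
  a <- if (sum(th^2) == 0) 0 else sum(th^3) / (6 * sum(th^2)^(3 / 2))
  srt <- sort(boot)
  q_interp <- function(p) {
    h <- (B - 1) * p + 1
    lo <- floor(h)
    srt[lo] + (h - lo) * (srt[ceiling(h)] - srt[lo])
  }
  ends <- sapply(c((1 - level) / 2, 1 - (1 - level) / 2), function(al) {
    z <- z0 + qnorm(al)
    q_interp(min(max(pnorm(z0 + z / (1 - a * z)), 0), 1))
  })
  c(lower = ends[1], upper = ends[2])
}

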