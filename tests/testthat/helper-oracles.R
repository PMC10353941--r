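# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (and the survival/MASS wrappers they call).

# Log-rank O/E table computed by direct enumeration over event times,
# Breslow-style aggregation of ties.
log_rank_oracle <- function(times, events, group) {
  group <- as.integer(as.factor(group)) - 1L  # 0/1
  ts <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Proportional-odds negative log-likelihood for a 3-level outcome and a
# single covariate; minimized with optim as a brute-force ML oracle.
polr_nll_oracle <- function(y, x) {
  # y in 1..3
  nll <- function(par) {
    z1 <- par[1]; z2 <- par[1] + exp(par[2]); b <- par[3]
    p1 <- stats::plogis(z1 - b * x)
    p2 <- stats::plogis(z2 - b * x)
    p <- cbind(p1, p2 - p1, 1 - p2)
    -sum(log(p[cbind(seq_along(y), y)]))
  }
  fit <- stats::optim(c(-0.5, 0, 0), nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  list(beta = fit$par[3], nll = fit$value)
}

# Brute-force weighted median: scan cumulative weights on the sorted betas
# and interpolate at 0.5 directly.
weighted_median_scan <- function(beta, weight) {
  ord <- order(beta)
  b <- beta[ord]
  w <- weight[ord] / sum(weight)
  s <- numeric(length(b))
  acc <- 0
  for (j in seq_along(b)) {
    s[j] <- acc + w[j] / 2
    acc <- acc + w[j]
  }
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  j <- max(which(s <= 0.5))
  b[j] + (0.5 - s[j]) / (s[j + 1] - s[j]) * (b[j + 1] - b[j])
}

# Expand a 2x2 table (a = exposed cases, b = exposed controls,
# c = unexposed cases, d = unexposed controls) into subject rows.
expand_2x2 <- function(a, b, c, d) {
  data.frame(
    y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    x = c(rep(1, a + b), rep(0, c + d))
  )
}
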