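# Independent brute-force oracles used to freeze expected values. These
# deliberately share no code with the implementation paths they check.

# Two-sided Fisher p by full hypergeometric enumeration from factorials.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  tab_p <- function(x)
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  probs <- vapply(lo:hi, tab_p, numeric(1))
  p_obs <- tab_p(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Cox partial log-likelihood for untied data (Breslow = Efron here).
oracle_cox_loglik <- function(beta, time, status, x) {
  ord <- order(time)
  time <- time[ord]; status <- status[ord]; x <- x[ord]
  eta <- beta * x
  ll <- 0
  for (i in seq_along(time)) {
    if (status[i] != 1L) next
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Harrell concordance by exhaustive pair enumeration.
oracle_c_index <- function(time, status, risk) {
  conc <- comp <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ti <- time[i]; tj <- time[j]
    if (ti == tj) next
    short <- if (ti < tj) i else j
    long <- if (ti < tj) j else i
    if (status[short] != 1L) next
    comp <- comp + 1
    if (risk[short] > risk[long]) conc <- conc + 1
    else if (risk[short] == risk[long]) conc <- conc + 0.5
  }
  conc / comp
}

# Cumulative/dynamic AUC at horizon t without censoring: pair counting.
oracle_cd_auc <- function(time, status, risk, t) {
  case <- which(time <= t & status == 1L)
  ctrl <- which(time > t)
  num <- 0
  for (i in case) num <- num + sum(risk[i] > risk[ctrl]) +
    0.5 * sum(risk[i] == risk[ctrl])
  num / (length(case) * length(ctrl))
}

# Dense grid minimization of the one-class objective on 2-gene instances,
# refined once around the coarse optimum.
oracle_oclr_grid <- function(X, l1 = 0, l2 = 1, lim = 2, step = 0.02) {
  obj <- function(w1, w2) {
    s <- w1 * X[1, ] + w2 * X[2, ]
    mean(log1p(exp(-s))) + l1 * (abs(w1) + abs(w2)) + (l2 / 2) * (w1^2 + w2^2)
  }
  scan <- function(c1, c2, half, by) {
    g1 <- seq(c1 - half, c1 + half, by = by)
    g2 <- seq(c2 - half, c2 + half, by = by)
    vals <- outer(g1, g2, Vectorize(obj))
    ij <- arrayInd(which.min(vals), dim(vals))
    list(w = c(g1[ij[1]], g2[ij[2]]), f = min(vals))
  }
  coarse <- scan(0, 0, lim, step)
  scan(coarse$w[1], coarse$w[2], 2 * step, step / 40)
}

# Direct summation of the single-sample enrichment formula.
oracle_ssgsea_es <- function(expr, set_mask, alpha) {
  N <- length(expr)
  nu <- rank(expr)
  ord <- order(expr, decreasing = TRUE)
  inset <- set_mask[ord]
  num <- den <- 0
  p_out_step <- 1 / (N - sum(set_mask))
  es <- 0; p_in <- 0; p_out <- 0
  wsum <- sum(nu[ord][inset]^alpha)
  for (i in seq_len(N)) {
    if (inset[i]) p_in <- p_in + nu[ord][i]^alpha / wsum
    else p_out <- p_out + p_out_step
    es <- es + (p_in - p_out)
  }
  es
}
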