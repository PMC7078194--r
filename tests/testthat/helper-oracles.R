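# Independent oracles used across the suite. Constants are hard-coded NIST
# values, kept separate from the package's own isotope table.

NIST <- list(
  m12C = 12, m13C = 13.00335484,
  mH = 1.00782503, m2H = 2.01410178,
  m14N = 14.00307401, m15N = 15.00010890,
  mO = 15.99491462, mP = 30.97376200, mS = 31.97207117
)

# brute-force per-atom mass: every atom contributes its own isotope mass
oracle_mass <- function(counts, n13C = 0, n15N = 0) {
  with(NIST, {
    sum(rep(m13C, n13C), rep(m12C, counts[["C"]] - n13C)) +
      sum(rep(m15N, n15N), rep(m14N, counts[["N"]] - n15N)) +
      sum(rep(mH, counts[["H"]])) + sum(rep(mO, counts[["O"]])) +
      sum(rep(mP, counts[["P"]])) + sum(rep(mS, counts[["S"]]))
  })
}

# multinomial enumeration over individual atoms: probability that a molecule
# with true label state (c0, n0) is observed at (c, n) given per-atom heavy
# probabilities (aC for the 5 - c0 unlabeled carbons etc.)
oracle_conv_prob <- function(nC, nN, c0, n0, c_obs, n_obs, aC, aN) {
  freeC <- nC - c0
  freeN <- nN - n0
  pc <- 0
  for (bits in 0:(2^freeC - 1)) {
    k <- sum(as.integer(intToBits(bits)[seq_len(max(freeC, 1))]))
    if (freeC == 0) k <- 0
    if (k + c0 == c_obs) pc <- pc + aC^k * (1 - aC)^(freeC - k)
    if (freeC == 0) break
  }
  pn <- 0
  for (bits in 0:(2^freeN - 1)) {
    k <- sum(as.integer(intToBits(bits)[seq_len(max(freeN, 1))]))
    if (freeN == 0) k <- 0
    if (k + n0 == n_obs) pn <- pn + aN^k * (1 - aN)^(freeN - k)
    if (freeN == 0) break
  }
  pc * pn
}

# Efron-approximation Cox partial log-likelihood for a binary covariate,
# tabulated directly from the risk sets
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(exp(beta * x[R]))
    sD <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (j in 0:(d - 1)) ll <- ll - log(sR - (j / d) * sD)
  }
  ll
}

# exhaustive grid search of the partial likelihood: coarse pass then 1e-4 grid
oracle_cox_grid <- function(x, time, event, lo = -5, hi = 5) {
  coarse <- seq(lo, hi, by = 0.01)
  ll <- vapply(coarse, oracle_cox_loglik, numeric(1), x = x, time = time, event = event)
  if (diff(range(ll)) < 1e-8) {
    return(NA_real_) # flat likelihood: no between-group information
  }
  b0 <- coarse[which.max(ll)]
  fine <- seq(max(lo, b0 - 0.02), min(hi, b0 + 0.02), by = 1e-4)
  llf <- vapply(fine, oracle_cox_loglik, numeric(1), x = x, time = time, event = event)
  fine[which.max(llf)]
}

# log-rank observed-minus-expected tabulation at each event time
oracle_logrank <- function(group, time, event) {
  g1 <- group == levels(factor(group))[2]
  OE <- 0
  V <- 0
  O <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    OE <- OE + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - OE)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# random small survival datasets for the grid-search comparison
random_toy_surv <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    group = factor(sample(c("low", "high"), n, replace = TRUE), levels = c("low", "high")),
    time = sample(1:20, n, replace = TRUE),
    event = sample(0:1, n, replace = TRUE)
  )
}

# flatten a MID tibble in a correction-matrix layout order
mid_vector_for_test <- function(mid, layout) {
  key <- paste(layout$n13C, layout$n15N)
  v <- stats::setNames(numeric(nrow(layout)), key)
  v[paste(mid$n13C, mid$n15N)] <- mid$fraction
  unname(v)
}

random_mid_grid <- function(maxC, maxN, seed) {
  set.seed(seed)
  f <- stats::runif((maxC + 1) * (maxN + 1))
  f <- f / sum(f)
  tidyr::expand_grid(n15N = 0:maxN, n13C = 0:maxC) |>
    dplyr::mutate(fraction = f) |>
    dplyr::select(n13C, n15N, fraction)
}
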