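# Independent oracles used across the suite. These deliberately re-derive
# quantities by literal enumeration, without reusing the package's
# vectorized implementations.

# Null-model working response by brute-force enumeration of risk sets.
brute_working_response <- function(time, status, strict = FALSE) {
  ft <- sort(unique(time[status == 1]))
  n <- length(time)
  s <- numeric(length(ft))
  for (i in seq_along(ft)) {
    cnt <- 0
    for (j in seq_len(n))
      if ((strict && time[j] > ft[i]) || (!strict && time[j] >= ft[i]))
        cnt <- cnt + 1
    s[i] <- cnt
  }
  score <- numeric(n); weights <- numeric(n)
  for (k in seq_len(n)) {
    acc <- 0; w <- 0
    for (i in seq_along(ft)) {
      inC <- if (strict) ft[i] < time[k] else ft[i] <= time[k]
      if (inC) { acc <- acc + 1 / s[i]; w <- w + (s[i] - 1) / s[i]^2 }
    }
    score[k] <- status[k] - acc
    weights[k] <- w
  }
  list(risk_counts = s, score = score, weights = weights)
}

# Negative log Breslow partial likelihood by direct product-form evaluation.
brute_neg_loglik <- function(x, time, status, beta) {
  lp <- drop(as.matrix(x) %*% beta)
  ft <- sort(unique(time[status == 1]))
  val <- 0
  for (t_i in ft) {
    risk <- which(time >= t_i)
    fail <- which(status == 1 & time == t_i)
    for (j in fail) val <- val - lp[j] + log(sum(exp(lp[risk])))
  }
  val
}

# Gradient of the averaged negative log partial likelihood; used for KKT
# verification of penalized fits.
cox_grad <- function(x, time, status, beta) {
  x <- as.matrix(x)
  lp <- drop(x %*% beta)
  w <- exp(lp)
  ft <- sort(unique(time[status == 1]))
  g <- numeric(ncol(x))
  for (t_i in ft) {
    risk <- which(time >= t_i)
    fail <- which(status == 1 & time == t_i)
    wbar <- colSums(x[risk, , drop = FALSE] * w[risk]) / sum(w[risk])
    for (j in fail) g <- g - (x[j, ] - wbar)
  }
  g / length(time)
}

# Harrell's C by pair enumeration.
brute_cindex <- function(time, status, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && status[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Small random survival dataset with at least one event.
random_dataset <- function(n, p, seed, censor_frac = 0.3) {
  set.seed(seed)
  repeat {
    x <- matrix(rnorm(n * p), n, p)
    time <- rexp(n)
    status <- as.integer(runif(n) > censor_frac)
    if (sum(status) >= 1) break
  }
  surv_dataset(x, time, status)
}
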