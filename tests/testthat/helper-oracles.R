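# Independent oracles and fixture builders used across the suite.

# naive long-truncation FPT series (both representations, >= 100 terms),
# independent of the C++ implementation
oracle_fpt_lower <- function(t, a, z, nu, s = 1, K = 150) {
  vapply(t, function(tt) {
    if (tt <= 0) return(0)
    as <- a / s
    ts <- tt / as^2
    w <- z
    f_small <- sum((w + 2 * (-K:K)) * exp(-(w + 2 * (-K:K))^2 / (2 * ts))) /
      sqrt(2 * pi * ts^3)
    f_large <- pi * sum((1:K) * exp(-(1:K)^2 * pi^2 * ts / 2) *
                          sin((1:K) * pi * w))
    exp(-(nu / s) * (a / s) * w - (nu / s)^2 * tt / 2) *
      mean(c(f_small, f_large)) / as^2
  }, numeric(1))
}

# brute-force pair enumeration for Kruskal's gamma
oracle_gamma <- function(x, y) {
  C <- D <- 0
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0 || sy == 0) next
    if (sx == sy) C <- C + 1 else D <- D + 1
  }
  if (C + D == 0) return(NA_real_)
  (C - D) / (C + D)
}

# small synthetic experiment table (balanced design, fixed seed)
make_trials <- function(n_per = 30, L = 2, K = 3, seed = 42,
                        subjects = 1) {
  set.seed(seed)
  rows <- expand.grid(subject = seq_len(subjects),
                      stimulus = c(-1, 1), condition = seq_len(L),
                      i = seq_len(n_per))
  n <- nrow(rows)
  acc <- plogis(0.8 * rows$condition)
  correct <- rbinom(n, 1, acc)
  response <- rows$stimulus * (2 * correct - 1)
  data.frame(subject = rows$subject, stimulus = rows$stimulus,
             condition = rows$condition, response = response,
             rt = round(runif(n, 0.4, 2.5), 3),
             rating = sample(1:K, n, replace = TRUE),
             correct = correct)
}

# deterministic parameter rows for density checks
par_2dsd <- function() {
  data.frame(model = "2DSD", a = 1.6, z = 0.48, sz = 0.2, snu = 0.5,
             tau = 0.8, t0 = 0.3, st0 = 0.15, d1 = 0.4, d2 = 1.1,
             thetaLower1 = 0.3, thetaLower2 = 1.2,
             thetaUpper1 = 0.4, thetaUpper2 = 1.4)
}

par_irmt <- function() {
  data.frame(model = "IRMt", A = 1.3, B = 1.5, wX = 0.5, wRT = 0.3,
             wInt = 0.2, t0 = 0.25, st0 = 0.1, d1 = 0.5, d2 = 1.2,
             thetaLower1 = 0.8, thetaLower2 = 1.6,
             thetaUpper1 = 0.9, thetaUpper2 = 1.8)
}

par_mtlnr <- function() {
  data.frame(model = "MTLNR", mu_d1 = 0.5, mu_d2 = 0.6, s1 = 0.6,
             s2 = 0.7, rho = 0.3, t0 = 0.25, st0 = 0.1,
             d1 = 0.4, d2 = 0.9,
             thetaLower1 = 0.3, thetaLower2 = 0.9,
             thetaUpper1 = 0.35, thetaUpper2 = 1.0)
}
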