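test_that("rho = 0 race density equals the independent product form", {
  # independent oracle: inverse-Gaussian FPT of the winner times the
  # sub-threshold survival/position law of the loser (reflection formula)
  A <- 1.2; B <- 1.6; mu1 <- 0.9; mu2 <- -0.4
  ig <- function(t, K, mu) K / sqrt(2 * pi * t^3) *
    exp(-(K - mu * t)^2 / (2 * t))
  surv <- function(t, K, mu) pnorm((K - mu * t) / sqrt(t)) -
    exp(2 * mu * K) * pnorm((-K - mu * t) / sqrt(t))
  t <- seq(0.05, 6, by = 0.05)
  ref <- ig(t, A, mu1) * surv(t, B, mu2)
  got <- dIRM(t, 1, -Inf, Inf, mu1, mu2, A, B)
  expect_lt(max(abs(ref - got)), 1e-12)

  # position law: gap density at fixed b
  gap_ref <- function(t, b) ig(t, A, mu1) *
    (dnorm(B - b, mu2 * t, sqrt(t)) -
       exp(2 * mu2 * B) * dnorm(B - b - 2 * B, mu2 * t, sqrt(t)))
  b <- seq(0.1, 3, by = 0.3)
  expect_equal(dfpt_race(rep(0.8, length(b)), 1, b, A, B, mu1, mu2),
               gap_ref(0.8, b), tolerance = 1e-12)
})

test_that("race density basics and invariants", {
  expect_equal(dfpt_race(-0.5, 1, 0.3, 1, 1, 0.5, 0.5), 0)
  expect_error(dIRMt(1, 1, 0, 1, 1, -1, 1, 1, wX = 0.5, wRT = 0.4,
                     wInt = 0.2), "sum to 1")
  expect_error(rtconf:::.d_race(1, 1L, 0, 1, 1, -1, 1, 1, 1, 1, -0.3,
                                1, 0, 0, 0, 0, FALSE, 3), "rho")

  # exchangeability: symmetric parameters give identical winner densities
  t <- seq(0.1, 3, by = 0.1)
  for (rho in c(0, -0.5)) {
    d1 <- rtconf:::.d_race(t, rep(1L, length(t)), 0.2, 0.9, 0.8, -0.8,
                           1.4, 1.4, 1, 1, rho, 1, 0, 0, 0, 0, FALSE, 4)
    d2 <- rtconf:::.d_race(t, rep(2L, length(t)), 0.2, 0.9, -0.8, 0.8,
                           1.4, 1.4, 1, 1, rho, 1, 0, 0, 0, 0, FALSE, 4)
    expect_equal(d1, d2, tolerance = 1e-12)
  }

  # swapping accumulators together with response relabeling is a no-op
  d12 <- dPCRMt(t, 1, 0.3, 1.5, 0.7, -0.2, 1.2, 1.6, wX = 0.5, wRT = 0.3,
                wInt = 0.2, t0 = 0.1, st0 = 0.2)
  d21 <- dPCRMt(t, 2, 0.3, 1.5, -0.2, 0.7, 1.6, 1.2, wX = 0.5, wRT = 0.3,
                wInt = 0.2, t0 = 0.1, st0 = 0.2)
  expect_equal(d12, d21, tolerance = 1e-12)

  # increasing th2 never decreases the density
  lo <- dPCRMt(1.1, 1, 0.2, 0.8, 0.7, -0.7, 1.3, 1.3, wX = 0.4,
               wRT = 0.4, wInt = 0.2)
  hi <- dPCRMt(1.1, 1, 0.2, 1.6, 0.7, -0.7, 1.3, 1.3, wX = 0.4,
               wRT = 0.4, wInt = 0.2)
  expect_gte(hi, lo)
})

test_that("gap density integrates to the marginal FPT density", {
  A <- 1.2; B <- 1.6; mu1 <- 0.9; mu2 <- -0.4
  bgrid <- seq(5e-4, 15, by = 1e-3)
  for (rho in c(0, -0.5)) {
    g <- dfpt_race(rep(0.7, length(bgrid)), 1, bgrid, A, B, mu1, mu2,
                   rho = rho)
    m <- rtconf:::.d_race(0.7, 1L, -Inf, Inf, mu1, mu2, A, B, 1, 1, rho,
                          1, 0, 0, 0, 0, FALSE, 4)
    expect_equal(sum(g) * 1e-3, m, tolerance = 1e-5)
  }
})

test_that("weights (1,0,0) reduce the time-dependent model to IRM/PCRM", {
  t <- seq(0.2, 3, by = 0.28)
  for (rho in c(0, -0.5)) {
    a <- rtconf:::.d_race(t, rep(1L, length(t)), 0.3, 1.2, 0.8, -0.5,
                          1.2, 1.5, 1, 1, rho, 1, 0, 0, 0.2, 0.1, TRUE, 4)
    b <- rtconf:::.d_race(t, rep(1L, length(t)), 0.3, 1.2, 0.8, -0.5,
                          1.2, 1.5, 1, 1, rho, 1, 0, 0, 0.2, 0.1, FALSE, 4)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("rho = -0.5 choice probabilities match an Euler-Maruyama oracle", {
  set.seed(99)
  n <- 40000
  sim <- rRM(n, mu1 = 0.9, mu2 = -0.4, A = 1.2, B = 1.6, rho = -0.5,
             wX = 0.5, wRT = 0.3, wInt = 0.2, time_dependent = TRUE,
             delta = 0.001, maxrt = 20)
  p1_sim <- mean(sim$response == 1)
  g <- seq(0.005, 15, by = 0.01)
  p1 <- sum(rtconf:::.d_race(g, rep(1L, length(g)), -Inf, Inf,
                             rep(0.9, length(g)), rep(-0.4, length(g)),
                             1.2, 1.6, 1, 1, -0.5, 0.5, 0.3, 0.2,
                             0, 0, TRUE, 4)) * 0.01
  expect_lt(abs(p1_sim - p1), 3 * sqrt(p1 * (1 - p1) / n))
  # a joint confidence-bin cell
  pb_sim <- mean(sim$response == 1 & sim$conf > 0.8 & sim$conf <= 1.5)
  pb <- sum(rtconf:::.d_race(g, rep(1L, length(g)), 0.8, 1.5,
                             rep(0.9, length(g)), rep(-0.4, length(g)),
                             1.2, 1.6, 1, 1, -0.5, 0.5, 0.3, 0.2,
                             0, 0, TRUE, 4)) * 0.01
  expect_lt(abs(pb_sim - pb), 3 * sqrt(pb * (1 - pb) / n))
})
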