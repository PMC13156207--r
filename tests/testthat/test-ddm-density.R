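test_that("FPT density matches a naive long-truncation series oracle", {
  t <- seq(0.05, 4, by = 0.05)
  got <- dfpt_ddm(t, -1, a = 2, z = 0.5, nu = 1, precision = 6)
  ref <- oracle_fpt_lower(t, a = 2, z = 0.5, nu = 1)
  expect_lt(max(abs(got - ref)), 1e-9)

  # asymmetric start and diffusion constant
  got2 <- dfpt_ddm(t, 1, a = 1.4, z = 0.35, nu = -0.6, s = 1.3,
                   precision = 6)
  ref2 <- oracle_fpt_lower(t, a = 1.4, z = 1 - 0.35, nu = 0.6, s = 1.3)
  expect_lt(max(abs(got2 - ref2)), 1e-9)
})

test_that("FPT density basics: negative times, symmetry, invariants", {
  expect_equal(dfpt_ddm(-0.1, 1, a = 2, z = 0.5), 0)
  t <- seq(0.1, 3, by = 0.1)
  up <- dfpt_ddm(t, 1, a = 2, z = 0.5, nu = 0)
  lo <- dfpt_ddm(t, -1, a = 2, z = 0.5, nu = 0)
  expect_equal(up, lo)
  expect_error(dfpt_ddm(1, 1, a = -1, z = 0.5), "invalid")
  expect_error(dfpt_ddm(1, 1, a = 1, z = 0.5, sz = 1.2), "invalid")
})

test_that("marginalizing confidence recovers the FPT density", {
  t <- seq(0.2, 3, by = 0.2)
  for (tau in c(0, 0.7)) {
    full <- ddynaViTE(t, 1, -Inf, Inf, a = 1.8, z = 0.45, nu = 0.8,
                      sz = 0.2, snu = 0.6, tau = tau, w = 0.55,
                      lambda = 0.4, sigvis = 0.4, svis = 0.8,
                      precision = 5)
    fpt <- dfpt_ddm(t, 1, a = 1.8, z = 0.45, sz = 0.2, nu = 0.8,
                    snu = 0.6, precision = 5)
    expect_equal(full, fpt, tolerance = 1e-6)
  }
  # zero-width interval has zero probability
  expect_equal(ddynaViTE(1, 1, 0.5, 0.5, a = 1.8, z = 0.45, nu = 0.8,
                         tau = 0.5, snu = 0.3), 0)
  expect_error(ddynaViTE(1, 1, 1, 0.5, a = 1.8, z = 0.5, nu = 1), "th1")
})

test_that("confidence bins are additive", {
  t <- seq(0.3, 2.5, by = 0.2)
  args <- list(a = 1.6, z = 0.5, nu = 0.7, sz = 0.15, snu = 0.4,
               tau = 0.9, w = 0.6, lambda = 0.3, sigvis = 0.3, svis = 0.9,
               precision = 5)
  d13 <- do.call(ddynaViTE, c(list(t, 1, -0.5, 1.5), args))
  d12 <- do.call(ddynaViTE, c(list(t, 1, -0.5, 0.4), args))
  d23 <- do.call(ddynaViTE, c(list(t, 1, 0.4, 1.5), args))
  expect_equal(d13, d12 + d23, tolerance = 1e-10)
})

test_that("special cases agree with the general dynaViTE density", {
  set.seed(31)
  t <- runif(100, 0.3, 3)
  R <- sample(c(-1, 1), 100, replace = TRUE)
  th1 <- runif(100, -0.5, 0.5); th2 <- th1 + runif(100, 0.1, 1.5)
  # dynWEV == dynaViTE at lambda = 0
  for (i in 1:3) {
    a <- runif(1, 1, 2.5); z <- runif(1, 0.4, 0.6); nu <- runif(1, 0.2, 1.5)
    sz <- runif(1, 0, 0.2); snu <- runif(1, 0, 0.8); tau <- runif(1, 0.2, 1)
    w <- runif(1, 0.3, 0.9); sv <- runif(1, 0.3, 1); sig <- runif(1, 0, 0.6)
    expect_equal(
      ddynWEV(t, R, th1, th2, a, z, nu, sz, snu, tau, w, abs(nu), sig, sv),
      ddynaViTE(t, R, th1, th2, a, z, nu, sz, snu, tau, w, lambda = 0,
                abs(nu), sig, sv),
      tolerance = 1e-12)
    # 2DSD == dynaViTE at lambda = 0, w = 1 (visibility ignored)
    expect_equal(
      d2DSD(t, R, th1, th2, a, z, nu, sz, snu, tau),
      ddynaViTE(t, R, th1, th2, a, z, nu, sz, snu, tau, w = 1, lambda = 0,
                muv = 99, sigvis = 3, svis = 2),
      tolerance = 1e-12)
    # DDConf == dynaViTE at w = 1, tau = 0, lambda = 0.5
    expect_equal(
      dDDConf(t, R, pmax(th1, 0.05), pmax(th1, 0.05) + 0.5, a, z, nu, sz,
              snu),
      ddynaViTE(t, R, pmax(th1, 0.05), pmax(th1, 0.05) + 0.5, a, z, nu,
                sz, snu, tau = 0, w = 1, lambda = 0.5, muv = 99,
                sigvis = 3, svis = 2),
      tolerance = 1e-12)
  }
})

test_that("joint density normalizes over responses, bins and time", {
  # one fixed parameter set; quadrature over a long grid
  grid <- seq(0.005, 25, by = 0.01)
  th <- c(-Inf, 0.4, 1.2, Inf)
  tot <- 0
  for (R in c(-1, 1)) for (k in 1:3) {
    d <- ddynaViTE(grid, R, th[k], th[k + 1], a = 1.8, z = 0.45, nu = 0.8,
                   sz = 0.2, snu = 0.6, tau = 1, w = 0.55, lambda = 0.4,
                   sigvis = 0.4, svis = 0.8, t0 = 0.3, st0 = 0.2,
                   precision = 4)
    tot <- tot + sum(d) * 0.01
  }
  expect_equal(tot, 1, tolerance = 1e-3)
})

test_that("density refines with the precision argument", {
  t <- seq(0.3, 2.5, by = 0.1)
  ref <- ddynaViTE(t, 1, 0.2, 1.1, a = 1.7, z = 0.45, nu = 0.6, sz = 0.25,
                   snu = 0.5, tau = 0.8, w = 0.6, lambda = 0.2,
                   sigvis = 0.4, svis = 0.8, t0 = 0.2, st0 = 0.2,
                   precision = 8)
  errs <- vapply(c(3, 4, 5, 6), function(p) {
    mean(abs(ddynaViTE(t, 1, 0.2, 1.1, a = 1.7, z = 0.45, nu = 0.6,
                       sz = 0.25, snu = 0.5, tau = 0.8, w = 0.6,
                       lambda = 0.2, sigvis = 0.4, svis = 0.8, t0 = 0.2,
                       st0 = 0.2, precision = p) - ref))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
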