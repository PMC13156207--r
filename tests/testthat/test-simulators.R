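test_that("simulators are deterministic under a fixed seed", {
  a <- rdynaViTE(50, a = 1.5, z = 0.5, nu = 0.8, tau = 0.5, snu = 0.3,
                 seed = 11)
  b <- rdynaViTE(50, a = 1.5, z = 0.5, nu = 0.8, tau = 0.5, snu = 0.3,
                 seed = 11)
  expect_identical(a, b)
  r1 <- rRM(50, 0.5, -0.5, 1.2, 1.2, rho = -0.5, seed = 12)
  r2 <- rRM(50, 0.5, -0.5, 1.2, 1.2, rho = -0.5, seed = 12)
  expect_identical(r1, r2)
  m1 <- rMTLNR(50, 0.8, 0.2, 0.3, 0.3, 0.5, 0.5, seed = 13)
  m2 <- rMTLNR(50, 0.8, 0.2, 0.3, 0.3, 0.5, 0.5, seed = 13)
  expect_identical(m1, m2)
})

test_that("stopped simulations return response 0 with missing outcomes", {
  sim <- rdynaViTE(200, a = 2, z = 0.5, nu = 0, delta = 0.001,
                   maxrt = 0.01, seed = 5)
  expect_gt(mean(sim$response == 0), 0.95)
  expect_true(all(is.na(sim$rt[sim$response == 0])))
  expect_error(rdynaViTE(10, a = 1, z = 0.5, nu = 1, delta = -1), "delta")
  expect_error(rdynaViTE(0, a = 1, z = 0.5, nu = 1), "n")
})

test_that("simulated mean RT matches the density-implied mean", {
  # no across-trial variability, strong drift
  set.seed(21)
  sim <- rdynaViTE(40000, a = 1.6, z = 0.5, nu = 1.5, tau = 0, w = 1,
                   t0 = 0.3, delta = 5e-4, maxrt = 15)
  keep <- sim$response != 0
  g <- seq(5e-4, 15, by = 1e-3)
  dens <- dfpt_ddm(g, 1, 1.6, 0.5, nu = 1.5) + dfpt_ddm(g, -1, 1.6, 0.5,
                                                        nu = 1.5)
  m_dens <- sum(g * dens) / sum(dens) + 0.3
  expect_lt(abs(mean(sim$rt[keep]) - m_dens),
            3 * sd(sim$rt[keep]) / sqrt(sum(keep)) + 2e-3)
})

test_that("race confidence reduces to the loser's gap for weights (1,0,0)", {
  sim <- rRM(500, 0.6, -0.6, 1.1, 1.3, wX = 1, wRT = 0, wInt = 0,
             time_dependent = TRUE, seed = 3)
  ok <- sim$response != 0
  expect_equal(sim$conf[ok], sim$b[ok])
  # and symmetric parameters give balanced choices
  sym <- rRM(4000, 0.5, 0.5, 1.2, 1.2, seed = 4)
  expect_lt(abs(mean(sym$response == 1) - 0.5), 0.03)
})

test_that("MTLNR simulator: ballistic, positive confidence, no response 0", {
  sim <- rMTLNR(2000, 0.8, 0.2, 0.3, 0.5, 0.5, 0.7, rho_v = 0.3,
                t0 = 0.2, st0 = 0.2, seed = 6)
  expect_true(all(sim$response %in% c(1L, 2L)))
  expect_true(all(sim$conf > 0))
  expect_true(all(sim$rt >= sim$t_dec + 0.2))
  sym <- rMTLNR(4000, 0.5, 0.5, 0.4, 0.4, 0.6, 0.6, seed = 8)
  expect_lt(abs(mean(sym$response == 1) - 0.5), 0.03)
})

test_that("simulate_fit_row produces the full design and aggregations", {
  row <- par_irmt()
  sim <- simulate_fit_row(row, n = 100, seed = 9)
  expect_equal(nrow(sim), 100 * 2 * 2)  # n per stimulus x condition
  expect_setequal(unique(sim$condition), 1:2)
  expect_true(all(sim$rating[sim$response != 0] %in% 1:3))
  # ratings follow the thresholds: rating = sum(c > theta) + 1
  ok <- sim$response == 1
  th <- c(0.9, 1.8)
  expect_equal(sim$rating[ok],
               vapply(sim$conf[ok], function(cc) sum(cc > th) + 1L,
                      integer(1)))

  agg <- simulate_fit_row(row, n = 50, aggregate = TRUE, seed = 10)
  full <- simulate_fit_row(row, n = 50, seed = 10)
  expect_equal(sum(agg$n), sum(full$response != 0))

  g <- simulate_fit_row(row, n = 200, gamma = TRUE, seed = 11)
  expect_named(g, c("simus", "gamma"))
  expect_equal(nrow(g$gamma$accuracy), 2)  # one gamma per condition
  expect_true(all(abs(g$gamma$accuracy$gamma) <= 1, na.rm = TRUE))

  expect_error(simulate_fit_row(transform(row, model = "nope")),
               "unknown model")
})

test_that("kruskal_gamma matches brute-force pair enumeration", {
  expect_equal(kruskal_gamma(1:5, 1:5), 1)
  expect_equal(kruskal_gamma(1:5, 5:1), -1)
  expect_equal(kruskal_gamma(c(1, 2, 2, 3), c(1, 1, 2, 3)),
               oracle_gamma(c(1, 2, 2, 3), c(1, 1, 2, 3)))
  expect_true(is.na(kruskal_gamma(c(1, 1, 1), c(2, 1, 2))))
  set.seed(14)
  for (i in 1:20) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(kruskal_gamma(x, y), oracle_gamma(x, y))
  }
})
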