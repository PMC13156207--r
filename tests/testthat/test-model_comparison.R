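fits_2m <- function(bic1, bic2, subjects = length(bic1)) {
  rbind(data.frame(subject = seq_len(subjects), model = "m1", BIC = bic1),
        data.frame(subject = seq_len(subjects), model = "m2", BIC = bic2))
}

test_that("subject weights follow the closed form", {
  f <- fits_2m(c(100, 100), c(100, 102))
  w <- subject_modelweights(f)
  expect_equal(unlist(w[1, c("m1", "m2")]), c(m1 = 0.5, m2 = 0.5))
  expect_equal(w$m1[2], 1 / (1 + exp(-1)))
  expect_equal(w$m2[2], exp(-1) / (1 + exp(-1)))
  expect_equal(rowSums(w[, c("m1", "m2")]), c(1, 1))
  # invariant to adding a constant per subject
  f2 <- fits_2m(c(100, 100) + 37, c(100, 102) + 37)
  expect_equal(subject_modelweights(f2)[, -1], w[, -1])
  expect_error(subject_modelweights(f[-1, ]), "missing")
})

test_that("group BMS: null case and decisive case behave analytically", {
  # identical evidences: ep = pep = 1/M; bor grows toward 1 with the
  # number of subjects (0.71 at n = 8, 0.92 at n = 200
  # under the standard variational formulas)
  f <- fits_2m(rep(100, 200), rep(100, 200))
  b <- group_BMS_fit(f)
  expect_equal(as.numeric(b$ep), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(as.numeric(b$pep), c(0.5, 0.5), tolerance = 1e-9)
  expect_gt(b$bor, 0.9)
  expect_lt(group_BMS_fit(fits_2m(rep(100, 8), rep(100, 8)))$bor, b$bor)
  expect_equal(sum(b$model_probs), 1, tolerance = 1e-9)
  expect_equal(sum(b$fixed_effect_probs), 1, tolerance = 1e-9)

  # 10 subjects unanimously favoring m1 by dIC = 20
  f2 <- fits_2m(rep(100, 10), rep(120, 10))
  b2 <- group_BMS_fit(f2)
  expect_gt(b2$ep[1], 0.99)
  expect_lt(b2$bor, 0.05)
  # pep shrinkage identity holds exactly
  expect_equal(as.numeric(b2$pep),
               as.numeric((1 - b2$bor) * b2$ep + b2$bor / 2),
               tolerance = 1e-12)
  # free energy is non-decreasing over iterations
  expect_true(all(diff(b2$free_energy) > -1e-8))
})

test_that("Monte-Carlo exceedance matches the analytic Beta comparison", {
  alpha <- c(3.2, 1.7)
  ep_analytic <- rtconf:::.exceedance(alpha, 0)
  set.seed(2)
  g <- matrix(rgamma(2e6, shape = rep(alpha, each = 1e6)), 1e6, 2)
  ep_mc <- mean(g[, 1] / rowSums(g) > 0.5)
  expect_lt(abs(ep_analytic[1] - ep_mc), 0.005)

  # three models: MC path, probabilities sum to 1
  f3 <- rbind(fits_2m(c(100, 90), c(105, 95)),
              data.frame(subject = 1:2, model = "m3", BIC = c(101, 93)))
  b3 <- group_BMS_fit(f3, mc_samples = 2e5, seed = 3)
  expect_equal(sum(b3$ep), 1, tolerance = 1e-9)
  expect_equal(sum(b3$pep), 1, tolerance = 1e-6)
})

test_that("single-subject posterior mass follows the IC weight ranking", {
  # mean-field updates are sparsity-promoting for small prior mass, so the
  # exact-inference limit (model_probs -> IC weights) does not hold for
  # the standard algorithm; the added posterior mass (alpha - alpha0) sums
  # to the number of subjects and ranks models like the IC weights
  f <- fits_2m(100, 104, subjects = 1)
  b <- group_BMS_fit(f)
  w <- subject_modelweights(f)
  expect_equal(sum(b$alpha) - 2, 1, tolerance = 1e-6)
  expect_equal(order(b$alpha), order(unlist(w[1, c("m1", "m2")])))
  # and for a large symmetric prior the assignment is exactly the weights
  b2 <- group_BMS_fit(f, alpha0 = 1e6)
  expect_equal(as.numeric(b2$alpha - 1e6), as.numeric(w[1, c("m1", "m2")]),
               tolerance = 1e-3)
})
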