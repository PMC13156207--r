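test_that("drift mapping follows the fitting-layer conventions", {
  d <- c(0.5, 0.8, 1.2)
  # dynaViTE family: nu = S*d_l, mu_V = d_l
  m <- map_parameters(-1, 2, "dynaViTE", d)
  expect_equal(m$nu, -0.8); expect_equal(m$muv, 0.8)
  # race: (mu1, mu2) = (S*d_l, -S*d_l)
  m <- map_parameters(1, 1, "PCRMt", d)
  expect_equal(unlist(m), c(mu1 = 0.5, mu2 = -0.5))
  # MTLNR: rate mean of the stimulus-congruent accumulator
  m <- map_parameters(-1, 3, "MTLNR", d)
  expect_equal(unlist(m), c(mu_v1 = 0, mu_v2 = 1.2))
  m <- map_parameters(c(1, -1), c(1, 3), "MTLNR", d)
  expect_equal(m$mu_v1, c(0.5, 0)); expect_equal(m$mu_v2, c(0, 1.2))
})

test_that("free-parameter counts match the closed-form formulas", {
  expect_equal(count_free_parameters("dynaViTE", 3, 3), 18)
  expect_equal(count_free_parameters("IRMt", 3, 3), 13)
  expect_equal(count_free_parameters("PCRMt", 3, 3), 13)
  expect_equal(count_free_parameters("MTLNRfull", 3, 3), 17)
  expect_equal(count_free_parameters("MTLNR", 5, 5), 7 + 5 + 2 * 4)
  expect_equal(count_free_parameters("dynaViTE", 5, 5), 11 + 5 + 2 * 4)
  expect_equal(count_free_parameters("IRMt", 5, 5), 6 + 5 + 2 * 4)
  # symmetric thresholds remove K-1 parameters
  expect_equal(count_free_parameters("dynaViTE", 3, 3, sym_thetas = TRUE),
               16)
  expect_equal(count_free_parameters("dynaViTE", 3, 3,
                                     fixed = list(sym_thetas = TRUE)), 16)
  # user-fixed parameters are subtracted; unknown names ignored
  expect_equal(count_free_parameters("2DSD", 2, 4, fixed = list(z = 0.5)),
               7 + 2 + 6 - 1)
  expect_error(count_free_parameters("nope", 3, 3), "unknown model")
})

test_that("negative log-likelihood is -sum(log density) and additive", {
  row <- par_2dsd()
  tr <- data.frame(subject = 1, stimulus = 1, condition = factor(1, 1:2),
                   response = 1, rt = 1.2, rating = 2, correct = 1)
  attr(tr, "n_ratings") <- 3
  # single trial: exactly -log p of the matching density call
  p <- d2DSD(1.2, 1, 0.4, 1.4, a = 1.6, z = 0.48, nu = 0.4, sz = 0.2,
             snu = 0.5, tau = 0.8, t0 = 0.3, st0 = 0.15, precision = 3)
  expect_equal(as.numeric(neg_loglik(row, tr, "2DSD")), -log(p),
               tolerance = 1e-10)
  # duplicated data doubles the value
  tr2 <- rbind(tr, tr)
  attr(tr2, "n_ratings") <- 3
  expect_equal(as.numeric(neg_loglik(row, tr2, "2DSD")),
               2 * as.numeric(neg_loglik(row, tr, "2DSD")),
               tolerance = 1e-10)
  # zero-density trials are penalized finitely and counted
  tr_bad <- transform(tr, rt = 0.05)  # below t0
  attr(tr_bad, "n_ratings") <- 3
  v <- neg_loglik(row, tr_bad, "2DSD")
  expect_true(is.finite(v))
  expect_equal(attr(v, "n_zero"), 1)
})

test_that("parameter transforms are bijective on the admissible set", {
  tr <- rtconf:::.sim_to_trials(
    simulate_fit_row(par_2dsd(), n = 40, seed = 2), 3)
  for (model in c("2DSD", "dynaViTE", "IRMt", "MTLNR")) {
    stats <- rtconf:::.data_stats(tr, 3, FALSE)
    pm <- rtconf:::.make_par_map(model, list(), stats, FALSE, "none")
    set.seed(7)
    for (rep in 1:5) {
      x <- rnorm(pm$k_free)
      p1 <- pm$untransform(x)
      nat <- p1
      nat$d <- unlist(p1[paste0("d", 1:2)])
      nat$th <- list(`-1` = unlist(p1[paste0("thetaLower", 1:2)]),
                     `1` = unlist(p1[paste0("thetaUpper", 1:2)]))
      p2 <- pm$untransform(pm$transform(nat))
      for (nm in names(p1)[vapply(p1, is.numeric, logical(1))]) {
        expect_equal(p2[[nm]], p1[[nm]], tolerance = 1e-5, label = paste(model, nm))
      }
    }
  }
})

test_that("a small 2DSD fit satisfies the IC identities and constraints", {
  truth <- par_2dsd()
  tr <- rtconf:::.sim_to_trials(simulate_fit_row(truth, n = 40, seed = 3), 3)
  opts <- list(grid_size = 80, n_starts = 1, n_restarts = 1,
               max_evals = 150)
  fit <- fit_conf_model(tr, "2DSD", n_ratings = 3, opts = opts, seed = 4)
  expect_equal(fit$AIC, 2 * fit$negLogLik + 2 * fit$k)
  expect_equal(fit$BIC, 2 * fit$negLogLik + fit$k * log(fit$N))
  expect_equal(fit$AICc,
               fit$AIC + 2 * fit$k * (fit$k + 1) / (fit$N - fit$k - 1))
  expect_equal(fit$N, nrow(tr))
  expect_equal(fit$k, count_free_parameters("2DSD", 2, 3))
  # optimum is at least as good as every grid start
  grid <- initial_grid(tr, "2DSD", n_ratings = 3, opts = opts,
                       n_return = 5)
  expect_lte(fit$negLogLik, min(grid$negLogLik) + 1e-6)

  # fixed parameters propagate and reduce k
  fitz <- fit_conf_model(tr, "2DSD", fixed = list(z = 0.5), n_ratings = 3,
                         opts = opts, seed = 4)
  expect_equal(fitz$z, 0.5)
  expect_equal(fitz$k, fit$k - 1)

  # symmetric thresholds are exactly equal in the output
  fits <- fit_conf_model(tr, "2DSD", fixed = list(sym_thetas = TRUE),
                         n_ratings = 3, opts = opts, seed = 4)
  expect_equal(fits$k, fit$k - 2)
  expect_true(all(c("theta1", "theta2") %in% names(fits)))

  expect_error(fit_conf_model(tr, "2DSD", fixed = list(bogus = 1),
                              n_ratings = 3), "bogus")
})

test_that("unused extreme categories get sentinel thresholds", {
  truth <- par_2dsd()
  sim <- simulate_fit_row(truth, n = 60, seed = 5)
  sim$rating[sim$rating == 3] <- 2   # top category never used
  tr <- rtconf:::.sim_to_trials(sim, 3)
  fit <- fit_conf_model(tr, "2DSD", n_ratings = 3,
                        opts = list(grid_size = 60, n_starts = 1,
                                    n_restarts = 1, max_evals = 100),
                        seed = 6)
  expect_equal(fit$thetaLower2, Inf)
  expect_equal(fit$thetaUpper2, Inf)
  expect_equal(fit$k, count_free_parameters("2DSD", 2, 3) - 2)
})

test_that("grid search candidates are adequate near the generator", {
  set.seed(11)
  good <- 0
  n_sets <- 10
  truth <- sample_parameters("2DSD", n_sets, L = 2, K = 3, seed = 31)
  for (i in seq_len(n_sets)) {
    tr <- rtconf:::.sim_to_trials(
      simulate_fit_row(truth[i, ], n = 60, seed = 100 + i), 3)
    gen_nll <- as.numeric(neg_loglik(truth[i, ], tr, "2DSD"))
    grid <- initial_grid(tr, "2DSD", n_ratings = 3,
                         opts = list(grid_size = 700), n_return = 1)
    if (grid$negLogLik[1] <= 1.2 * gen_nll) good <- good + 1
  }
  expect_gte(good, 0.8 * n_sets)
})

test_that("fit_conf_models covers the subject x model grid", {
  tr <- rbind(
    cbind(simulate_fit_row(par_irmt(), n = 25, seed = 7), subject = "s1"),
    cbind(simulate_fit_row(par_irmt(), n = 25, seed = 8), subject = "s2"))
  tr <- tr[tr$response != 0, ]
  tr$correct <- as.integer(tr$stimulus == tr$response)
  tr <- ingest_trials(tr, n_ratings = 3)
  opts <- list(grid_size = 60, n_starts = 1, n_restarts = 1,
               max_evals = 120)
  fits <- fit_conf_models(tr, c("IRMt", "IRM"), n_ratings = 3,
                          opts = opts, seed = 10)
  expect_equal(nrow(fits), 4)
  expect_setequal(fits$model, c("IRMt", "IRM"))
  expect_false(any(fits$failed))
  # serial and parallel execution agree
  fits_par <- fit_conf_models(tr, c("IRMt", "IRM"), n_ratings = 3,
                              opts = opts, parallel = 2, seed = 10)
  expect_equal(fits_par$negLogLik, fits$negLogLik, tolerance = 1e-12)
  expect_error(fit_conf_models(tr, c("IRMt", "bogus")), "unknown model")
})
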