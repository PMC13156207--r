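# Simulation studies shipped with the package: parameter sampling for
# synthetic experiments, parameter recovery, model recovery, and the
# precision benchmark of the numeric density approximations.

#' Default parameter ranges for the synthetic-data sampler
#'
#' Ranges emulate empirical fits of binary discrimination experiments
#' (response times mostly below ~3 s, accuracies between ~60 and ~95
#' percent across difficulty levels).  Drifts are sampled as a first level
#' plus nonnegative increments, so discriminability increases across
#' levels.
#'
#' @param model model name.
#' @return named list of c(min, max) ranges.
#' @export
default_param_ranges <- function(model) {
  m <- .get_model(model)
  common <- list(t0 = c(0.2, 0.5), st0 = c(0.05, 0.3),
                 d1 = c(0.2, 0.8), dstep = c(0.2, 0.8))
  fam <- switch(m$family,
    ddm = list(a = c(1.0, 2.5), z = c(0.4, 0.6), sz_rel = c(0, 0.7),
               snu = c(0.2, 1.0), tau = c(0.5, 1.5), w = c(0.35, 0.7),
               lambda = c(0.2, 1.0), svis = c(0.3, 1.2),
               sigvis = c(0.2, 0.8)),
    race = list(total = c(2, 4), ratio = c(0.4, 0.6), wX = c(0.25, 0.8),
                wRT_rel = c(0.1, 0.8), d1 = c(0.3, 1.0),
                dstep = c(0.3, 1.0)),
    mtlnr = list(mu_d1 = c(0.2, 1.0), mu_d2 = c(0.2, 1.0),
                 s1 = c(0.4, 1.0), s2 = c(0.4, 1.0), rho = c(-0.3, 0.6),
                 sigma_d1 = c(0.2, 0.6), sigma_d2 = c(0.2, 0.6),
                 rho_d = c(-0.3, 0.3), d1 = c(0.3, 0.8),
                 dstep = c(0.3, 0.8)))
  modifyList(common, fam)
}

.runif_r <- function(r) runif(1, r[1], r[2])

#' Sample generating parameter sets for simulation studies
#'
#' Parameters are drawn independently and uniformly within
#' \code{\link{default_param_ranges}}, with these exceptions: drifts are a
#' uniform first level plus uniform nonnegative increments (increasing
#' discriminability); starting-point variability is uniform over the
#' admissible range given z; the race confidence weights are drawn
#' sequentially on the simplex; race boundaries are drawn as total
#' separation and relative height.  Confidence thresholds are set at
#' quantiles of a simulated internal confidence variable at the target
#' rating proportions, so every category has mass.
#'
#' @param model model name (use \code{"MTLNRfull"} for the full MTLNR
#'   parameterization of the precision benchmark).
#' @param n_sets number of parameter sets.
#' @param L,K number of difficulty levels / rating categories.
#' @param ranges optional override of \code{\link{default_param_ranges}}.
#' @param rating_props target rating proportions (length K simplex;
#'   default equal).
#' @param n_cal trials simulated to calibrate thresholds.
#' @param delta_cal simulation step for the calibration runs.
#' @param seed optional seed.
#' @return data frame of parameter rows (one per set) with a \code{model}
#'   column, suitable for \code{\link{simulate_fit_row}}.
#' @export
sample_parameters <- function(model, n_sets, L = 2, K = 3, ranges = NULL,
                              rating_props = NULL, n_cal = 1200,
                              delta_cal = 0.002, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- .get_model(model)
  rg <- modifyList(default_param_ranges(model), if (is.null(ranges)) list()
                   else ranges)
  if (is.null(rating_props)) rating_props <- rep(1 / K, K)
  stopifnot(length(rating_props) == K, all(rating_props > 0))
  cum <- cumsum(rating_props / sum(rating_props))[-K]
  rows <- lapply(seq_len(n_sets), function(i) {
    p <- list(model = model)
    if (m$family == "ddm") {
      p$a <- .runif_r(rg$a); p$z <- .runif_r(rg$z)
      p$sz <- .runif_r(rg$sz_rel) * 2 * min(p$z, 1 - p$z)
      p$snu <- .runif_r(rg$snu)
      if ("tau" %in% m$base) p$tau <- .runif_r(rg$tau)
      if ("w" %in% m$base) p$w <- .runif_r(rg$w)
      if ("lambda" %in% m$base) p$lambda <- .runif_r(rg$lambda)
      if ("svis" %in% m$base) p$svis <- .runif_r(rg$svis)
      if ("sigvis" %in% m$base) p$sigvis <- .runif_r(rg$sigvis)
    } else if (m$family == "race") {
      total <- .runif_r(rg$total); ratio <- .runif_r(rg$ratio)
      p$A <- total * ratio; p$B <- total * (1 - ratio)
      if (m$time_dependent) {
        p$wX <- .runif_r(rg$wX)
        p$wRT <- .runif_r(rg$wRT_rel) * (1 - p$wX)
        p$wInt <- 1 - p$wX - p$wRT
      }
    } else {
      p$mu_d1 <- .runif_r(rg$mu_d1)
      p$mu_d2 <- if (model == "MTLNRfull") .runif_r(rg$mu_d2) else p$mu_d1 +
        runif(1, -0.2, 0.2)
      p$s1 <- .runif_r(rg$s1); p$s2 <- .runif_r(rg$s2)
      p$rho <- .runif_r(rg$rho)
      if (model == "MTLNRfull") {
        p$sigma_d1 <- .runif_r(rg$sigma_d1)
        p$sigma_d2 <- .runif_r(rg$sigma_d2)
        p$rho_d <- .runif_r(rg$rho_d)
      }
    }
    p$t0 <- .runif_r(rg$t0); p$st0 <- .runif_r(rg$st0)
    d <- .runif_r(rg$d1) + c(0, cumsum(runif(L - 1, rg$dstep[1],
                                             rg$dstep[2])))
    for (l in seq_len(L)) p[[paste0("d", l)]] <- d[l]
    # thresholds from quantiles of the simulated confidence variable
    th <- .calibrate_thresholds(p, model, L, cum, n_cal, delta_cal)
    for (k in seq_len(K - 1)) {
      p[[paste0("thetaLower", k)]] <- th$lower[k]
      p[[paste0("thetaUpper", k)]] <- th$upper[k]
    }
    as.data.frame(p)
  })
  do.call(rbind, rows)
}

.calibrate_thresholds <- function(p, model, L, cum, n_cal, delta_cal) {
  if (length(cum) == 0) return(list(lower = numeric(0), upper = numeric(0)))
  # provisional thresholds so simulate_fit_row can run; ratings are ignored
  K <- length(cum) + 1
  pp <- as.data.frame(p)
  for (k in seq_len(K - 1)) {
    pp[[paste0("thetaLower", k)]] <- k
    pp[[paste0("thetaUpper", k)]] <- k
  }
  n_per <- max(ceiling(n_cal / (2 * L)), 50)
  sim <- simulate_fit_row(pp, n = n_per, delta = delta_cal)
  sim <- sim[sim$response != 0, ]
  qs <- function(sel) {
    cc <- sim$conf[sel]
    if (sum(sel) < 30) cc <- sim$conf
    as.numeric(quantile(cc, cum, type = 8))
  }
  lo <- qs(sim$response == -1)
  up <- qs(sim$response == 1)
  mono <- function(v) cummax(v + (seq_along(v) - 1) * 1e-6)
  list(lower = mono(lo), upper = mono(up))
}

#' Lin's concordance correlation coefficient
#'
#' \eqn{2\,cov(x,y) / (var(x) + var(y) + (\bar x - \bar y)^2)} with
#' population (1/n) moments.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return value in [-1, 1]; \code{NA} when both variances and the mean
#'   difference are zero.
#' @export
ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den == 0) return(NA_real_)
  2 * cxy / den
}

#' Scaled and full-scale presets for the recovery studies
#'
#' The scaled preset keeps the suite desk-runnable; the full preset
#' reproduces the head-line simulation settings (50 sets, up to 500 trials
#' per cell, L = 5, K = 5) and is marked \code{desk_scale = FALSE}: it is
#' not run by the test suite.
#'
#' @return named list of preset parameter lists.
#' @export
recovery_presets <- function() {
  list(
    scaled = list(n_sets = 10, trials_per_cell = 100, L = 2, K = 3,
                  desk_scale = TRUE,
                  opts = list(grid_size = 600, n_starts = 2, n_restarts = 2,
                              max_evals = 600, precision = 3)),
    full = list(n_sets = 50, trials_per_cell = 500, L = 5, K = 5,
                desk_scale = FALSE,
                opts = list(grid_size = 12000, n_starts = 5, n_restarts = 5,
                            max_evals = 5000, precision = 3)))
}

#' Parameter recovery study
#'
#' Samples generating parameter sets, simulates data, refits the model and
#' reports Lin's CCC between generating and recovered values for every
#' free parameter.
#'
#' @param model model to study.
#' @param n_sets number of simulated data sets.
#' @param trials_per_cell trials per stimulus x condition cell.
#' @param L,K experiment dimensions.
#' @param fit_opts optimization budget (defaults to the scaled preset).
#' @param seed seed for the whole pipeline (sampling, simulation,
#'   fitting).
#' @return list with \code{ccc} (named vector), \code{truth} and
#'   \code{fits} data frames, and \code{runtime} seconds.
#' @export
run_parameter_recovery <- function(model, n_sets = 10,
                                   trials_per_cell = 100, L = 2, K = 3,
                                   fit_opts = NULL, seed = 1) {
  if (is.null(fit_opts)) fit_opts <- recovery_presets()$scaled$opts
  t_start <- Sys.time()
  truth <- sample_parameters(model, n_sets, L = L, K = K, seed = seed)
  fits <- list()
  for (i in seq_len(n_sets)) {
    sim <- simulate_fit_row(truth[i, ], n = trials_per_cell,
                            seed = seed + 131 * i)
    trials <- .sim_to_trials(sim, K)
    fits[[i]] <- fit_conf_model(trials, model, n_ratings = K,
                                opts = fit_opts, seed = seed + 977 * i,
                                subject = i)
  }
  fits <- .rbind_fill(fits)
  pars <- intersect(names(truth), names(fits))
  pars <- setdiff(pars, c("model"))
  cc <- vapply(pars, function(nm) {
    tv <- as.numeric(truth[[nm]]); fv <- as.numeric(fits[[nm]])
    ok <- is.finite(tv) & is.finite(fv)
    if (sum(ok) < 2 || sd(tv[ok]) == 0) return(NA_real_)
    ccc(tv[ok], fv[ok])
  }, numeric(1))
  list(ccc = cc, truth = truth, fits = fits,
       runtime = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
}

# simulated experiment table -> conf_trials
.sim_to_trials <- function(sim, K) {
  sim <- sim[sim$response != 0, ]
  tr <- data.frame(subject = 1, stimulus = sim$stimulus,
                   condition = factor(sim$condition),
                   response = sim$response, rt = sim$rt,
                   rating = sim$rating,
                   correct = as.integer(sim$stimulus == sim$response))
  attr(tr, "n_ratings") <- K
  attr(tr, "rating_info") <- list(
    K = K, used = list(`-1` = sort(unique(tr$rating[tr$response == -1])),
                       `1` = sort(unique(tr$rating[tr$response == 1]))))
  class(tr) <- c("conf_trials", "data.frame")
  tr
}

#' Model recovery study
#'
#' Simulates data from each generator model, fits all candidate models to
#' every data set, classifies by minimum BIC, AIC and AICc, and computes
#' the group-level protected exceedance probability per generator.
#'
#' @param models candidate (and generator) model names.
#' @inheritParams run_parameter_recovery
#' @return list with \code{misclassification} (one generator x chosen
#'   matrix per measure), \code{pep} (PEP of each generator model within
#'   its own simulated group), \code{fits}, and \code{runtime}.
#' @export
run_model_recovery <- function(models = c("2DSD", "IRMt"), n_sets = 10,
                               trials_per_cell = 100, L = 2, K = 3,
                               fit_opts = NULL, seed = 1) {
  if (is.null(fit_opts)) fit_opts <- recovery_presets()$scaled$opts
  t_start <- Sys.time()
  measures <- c("BIC", "AIC", "AICc")
  mis <- lapply(measures, function(m)
    matrix(0L, length(models), length(models),
           dimnames = list(generator = models, chosen = models)))
  names(mis) <- measures
  pep <- setNames(numeric(length(models)), models)
  all_fits <- list()
  for (gi in seq_along(models)) {
    gen <- models[gi]
    truth <- sample_parameters(gen, n_sets, L = L, K = K,
                               seed = seed + 100 * gi)
    gfits <- list()
    for (i in seq_len(n_sets)) {
      sim <- simulate_fit_row(truth[i, ], n = trials_per_cell,
                              seed = seed + 1000 * gi + 13 * i)
      trials <- .sim_to_trials(sim, K)
      for (cand in models) {
        gfits[[length(gfits) + 1]] <- fit_conf_model(
          trials, cand, n_ratings = K, opts = fit_opts,
          seed = seed + 5000 * gi + 17 * i, subject = i)
      }
    }
    gfits <- .rbind_fill(gfits)
    gfits$generator <- gen
    all_fits[[gi]] <- gfits
    for (ms in measures) {
      for (i in seq_len(n_sets)) {
        sub <- gfits[gfits$subject == i, ]
        chosen <- sub$model[which.min(sub[[ms]])]
        mis[[ms]][gen, chosen] <- mis[[ms]][gen, chosen] + 1L
      }
    }
    bms <- group_BMS_fit(gfits, measure = "BIC", seed = seed + gi)
    pep[gen] <- bms$pep[gen]
  }
  list(misclassification = mis, pep = pep, fits = .rbind_fill(all_fits),
       runtime = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
}

#' Precision benchmark of the density approximations
#'
#' Samples parameter sets (L = 3, K = 3 by default, as in the density
#' precision study), simulates trials, and computes the trial-wise joint
#' densities at several values of the \code{precision} argument.  Reports
#' the mean absolute difference to the reference precision and between
#' consecutive precision values, plus timings.
#'
#' @param model model name (\code{"MTLNRfull"} benchmarks the full MTLNR).
#' @param n_sets parameter sets. @param trials_per_cell trials per
#'   stimulus x condition cell (default 100: 600 trials at L = 3).
#' @param precision_values precisions to evaluate.
#' @param reference_precision reference (default 9).
#' @param L,K experiment dimensions.
#' @param seed seed.
#' @return data frame with one row per set x precision: \code{mae_ref},
#'   \code{mae_consecutive} (difference to the next smaller precision in
#'   the list), and \code{time} seconds.
#' @export
run_precision_benchmark <- function(model, n_sets = 5,
                                    trials_per_cell = 100,
                                    precision_values = seq(2, 7, 0.5),
                                    reference_precision = 9,
                                    L = 3, K = 3, seed = 1) {
  truth <- sample_parameters(model, n_sets, L = L, K = K, seed = seed)
  out <- list()
  for (i in seq_len(n_sets)) {
    row <- truth[i, ]
    sim <- simulate_fit_row(row, n = trials_per_cell,
                            seed = seed + 31 * i)
    trials <- .sim_to_trials(sim, K)
    dens <- function(prec) .trial_density(row, model, trials, prec, FALSE)
    t_ref <- system.time(ref <- dens(reference_precision))[["elapsed"]]
    prev <- NULL
    for (j in seq_along(precision_values)) {
      pv <- precision_values[j]
      tm <- system.time(dv <- dens(pv))[["elapsed"]]
      out[[length(out) + 1]] <- data.frame(
        set = i, precision = pv,
        mae_ref = mean(abs(dv - ref)),
        mae_consecutive = if (is.null(prev)) NA_real_
          else mean(abs(dv - prev)),
        time = tm, time_ref = t_ref)
      prev <- dv
    }
  }
  do.call(rbind, out)
}
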