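# Maximum-likelihood fitting: bijective transforms to an unconstrained
# space, data-driven grid-search initialization, restarted Nelder-Mead
# optimization, and information-criterion reporting.

.default_opts <- function(opts = list()) {
  modifyList(list(grid_size = 12000, n_starts = 5, n_restarts = 5,
                  max_evals = 5000, precision = 3), opts)
}

.data_stats <- function(trials, K, sym_thetas) {
  L <- nlevels(trials$condition)
  acc <- tapply(trials$correct, trials$condition, mean)
  used <- attr(trials, "rating_info")$used
  if (is.null(used)) {
    used <- list(`-1` = sort(unique(trials$rating[trials$response == -1])),
                 `1` = sort(unique(trials$rating[trials$response == 1])))
  }
  if (sym_thetas) used <- list(both = sort(unique(trials$rating)))
  # cumulative proportions at the fitted boundaries (between used categories)
  cum_props <- lapply(names(used), function(nm) {
    u <- used[[nm]]
    sel <- if (nm == "both") rep(TRUE, nrow(trials))
      else trials$response == as.integer(nm)
    pr <- sapply(u, function(k) mean(trials$rating[sel] == k))
    pr <- pr / sum(pr)
    cp <- cumsum(pr)[-length(pr)]
    pmin(pmax(cp, 0.02), 0.98)
  })
  names(cum_props) <- names(used)
  list(L = L, K = K, n = nrow(trials), minrt = min(trials$rt),
       q10 = quantile(trials$rt, 0.1), q50 = quantile(trials$rt, 0.5),
       q90 = quantile(trials$rt, 0.9),
       acc = pmin(pmax(as.numeric(acc), 0.5), 0.999),
       used = used, cum_props = cum_props)
}

# drift pattern across conditions from per-condition accuracy
.drift_pattern <- function(stats) {
  pmax(qnorm(pmin(pmax(stats$acc, 0.55), 0.995)), 0.15)
}

# -- bijective parameterization ---------------------------------------------

# Builds untransform (unconstrained -> natural named list, with fixed values
# substituted, derived parameters completed, and thresholds expanded to full
# K-1 vectors with sentinels for unused categories) and transform (natural
# candidate -> unconstrained coordinates).
.make_par_map <- function(model, fixed, stats, simult_conf, restr_tau) {
  m <- .get_model(model)
  sym <- isTRUE(fixed$sym_thetas)
  fixed <- fixed[setdiff(names(fixed), "sym_thetas")]
  base_free <- setdiff(m$base, names(fixed))
  L <- stats$L
  th_groups <- if (sym) "both" else c("-1", "1")
  n_bound <- sapply(th_groups, function(g) {
    u <- stats$used[[g]]
    max(length(u) - 1L, 0L)
  })
  minrt <- stats$minrt
  K <- stats$K

  nm_x <- c(base_free, paste0("d", seq_len(L)),
            unlist(lapply(seq_along(th_groups), function(i) {
              if (n_bound[i] == 0) return(character())
              paste0("th_", th_groups[i], "_", seq_len(n_bound[i]))
            })))

  first_positive <- m$family != "ddm"  # race/MTLNR thresholds are positive

  untransform <- function(x) {
    p <- as.list(fixed)
    i <- 0
    gx <- function() { i <<- i + 1; x[i] }
    for (nm in base_free) {
      p[[nm]] <- switch(nm,
        a = , A = , B = , snu = , svis = , sigvis = , st0 = ,
        s1 = , s2 = , lambda = exp(gx()),
        z = plogis(gx()),
        w = plogis(gx()),
        wX = plogis(gx()),
        wRT = NA,  # handled after wX below
        sz = NA,   # needs z
        tau = NA,  # may need t0
        t0 = 0.995 * minrt * plogis(gx()),
        rho = tanh(gx()),
        mu_d1 = , mu_d2 = gx())
      if (nm == "wRT") p$wRT <- (1 - p$wX) * plogis(gx())
      if (nm == "sz") {
        zz <- if (!is.null(p$z)) p$z else 0.5
        p$sz <- 1.99 * min(zz, 1 - zz) * plogis(gx())
      }
      if (nm == "tau") {
        bound <- if (identical(restr_tau, "simult_conf")) {
          tt0 <- if (!is.null(p$t0)) p$t0 else 0
          max(0.995 * (minrt - tt0), 1e-3)
        } else if (is.numeric(restr_tau)) restr_tau else Inf
        p$tau <- if (is.finite(bound)) bound * plogis(gx()) else exp(gx())
      }
    }
    if ("wX" %in% m$base) p$wInt <- max(1 - p$wX - p$wRT, 0)
    for (l in seq_len(L)) p[[paste0("d", l)]] <- exp(gx())
    th <- list()
    for (gi in seq_along(th_groups)) {
      nb <- n_bound[gi]
      if (nb == 0) { th[[th_groups[gi]]] <- numeric(0); next }
      b <- numeric(nb)
      b[1] <- if (first_positive) exp(gx()) else gx()
      if (nb > 1) for (j in 2:nb) b[j] <- b[j - 1] + 1e-6 + exp(gx())
      th[[th_groups[gi]]] <- b
    }
    # expand fitted boundaries to full K-1 thresholds with sentinels
    expand <- function(bounds, used) {
      full <- rep(NA_real_, K - 1)
      if (length(used) == 0) return(rep(Inf, K - 1))
      if (used[1] > 1) full[seq_len(used[1] - 1)] <- -Inf
      if (length(used) > 1) {
        for (j in seq_len(length(used) - 1)) {
          full[used[j]:(used[j + 1] - 1)] <- bounds[j]
        }
      }
      last <- used[length(used)]
      if (last <= K - 1) full[last:(K - 1)] <- Inf
      full
    }
    if (sym) {
      full <- expand(th$both, stats$used$both)
      for (k in seq_len(K - 1)) p[[paste0("theta", k)]] <- full[k]
    } else {
      flo <- expand(th$`-1`, stats$used$`-1`)
      fup <- expand(th$`1`, stats$used$`1`)
      for (k in seq_len(K - 1)) {
        p[[paste0("thetaLower", k)]] <- flo[k]
        p[[paste0("thetaUpper", k)]] <- fup[k]
      }
    }
    .complete_params(p, model)
  }

  # natural candidate: base params + d vector + fitted boundaries per group
  transform <- function(nat) {
    x <- numeric(0)
    for (nm in base_free) {
      v <- nat[[nm]]
      x <- c(x, switch(nm,
        a = , A = , B = , snu = , svis = , sigvis = , st0 = ,
        s1 = , s2 = , lambda = log(max(v, 1e-6)),
        z = qlogis(min(max(v, 1e-4), 1 - 1e-4)),
        w = , wX = qlogis(min(max(v, 1e-4), 1 - 1e-4)),
        wRT = qlogis(min(max(v / max(1 - nat$wX, 1e-6), 1e-4), 1 - 1e-4)),
        sz = {
          zz <- if (!is.null(nat$z)) nat$z else 0.5
          qlogis(min(max(v / (1.99 * min(zz, 1 - zz)), 1e-4), 1 - 1e-4))
        },
        tau = {
          bound <- if (identical(restr_tau, "simult_conf")) {
            tt0 <- if (!is.null(nat$t0)) nat$t0 else 0
            max(0.995 * (minrt - tt0), 1e-3)
          } else if (is.numeric(restr_tau)) restr_tau else Inf
          if (is.finite(bound)) qlogis(min(max(v / bound, 1e-4), 1 - 1e-4))
            else log(max(v, 1e-6))
        },
        t0 = qlogis(min(max(v / (0.995 * minrt), 1e-4), 1 - 1e-4)),
        rho = atanh(min(max(v, -0.999), 0.999)),
        mu_d1 = , mu_d2 = v))
    }
    d <- nat$d
    x <- c(x, log(pmax(d, 1e-6)))
    for (gi in seq_along(th_groups)) {
      nb <- n_bound[gi]
      if (nb == 0) next
      b <- nat$th[[th_groups[gi]]][seq_len(nb)]
      b <- cummax(b + (seq_len(nb) - 1) * 1e-8)  # enforce ascending
      x <- c(x, if (first_positive) log(max(b[1], 1e-4)) else b[1])
      if (nb > 1) x <- c(x, log(pmax(diff(b), 2e-6) - 1e-6))
    }
    stats::setNames(x, nm_x)
  }

  list(names = nm_x, untransform = untransform, transform = transform,
       k_free = length(nm_x), sym = sym, n_bound = n_bound,
       th_groups = th_groups)
}

# -- grid-search initialization ---------------------------------------------

# analytic anchor for confidence thresholds at the cumulative rating
# proportions, given core candidate parameters
.anchor_thresholds <- function(model, cand, stats, cum) {
  m <- .get_model(model)
  if (length(cum) == 0) return(numeric(0))
  d_mid <- mean(cand$d)
  if (m$family == "ddm") {
    p <- .complete_params(cand, model)
    t_med <- max(as.numeric(stats$q50) - p$t0 -
                   if (isTRUE(cand$simult_conf)) p$tau else 0, 0.08)
    ttau <- t_med + p$tau
    mm <- p$w * (p$a * (1 - p$z) + d_mid * p$tau) + (1 - p$w) * d_mid * ttau
    vv <- p$w^2 * (p$tau^2 * p$snu^2 + p$tau) +
      (1 - p$w)^2 * (p$sigvis^2 * ttau^2 + p$svis^2 * ttau)
    scale <- ttau^p$lambda
    if (vv > 1e-10) {
      th <- (mm + sqrt(vv) * qnorm(cum)) / scale
    } else {
      # degenerate confidence (DDConf): c decreasing in decision time, so
      # anchor thresholds at RT quantiles in reverse order
      tdec_q <- pmax(as.numeric(stats$q50) * (0.6 + 1.2 * (1 - cum)) - p$t0,
                     0.05)
      th <- p$a * (1 - p$z) / sqrt(tdec_q)
    }
  } else if (m$family == "race") {
    p <- .complete_params(cand, model)
    t_med <- max(as.numeric(stats$q50) - p$t0, 0.08)
    mean_b <- (p$A + p$B) / 2 + d_mid * t_med
    sd_b <- sqrt(t_med)
    if (m$time_dependent) {
      mm <- p$wX * mean_b + p$wRT / sqrt(t_med) + p$wInt * mean_b / sqrt(t_med)
      ss <- (p$wX + p$wInt / sqrt(t_med)) * sd_b
    } else {
      mm <- mean_b; ss <- sd_b
    }
    th <- mm + ss * qnorm(cum)
    th <- pmax(th, 1e-3 * seq_along(th))
  } else {
    sbar <- mean(c(cand$s1, cand$s2))
    th <- sqrt(2) * sbar * qnorm((1 + cum) / 2)
    th <- pmax(th, 1e-3 * seq_along(th))
  }
  cummax(th + (seq_along(th) - 1) * 1e-6)
}

# product grid of natural candidates for a model (documented anchor recipe:
# boundary, variability and timing anchors crossed with a drift scale; t0
# anchored below the minimum observed RT; drift pattern from per-condition
# accuracy; thresholds at observed rating proportions)
.grid_candidates <- function(model, fixed, stats, simult_conf, restr_tau) {
  m <- .get_model(model)
  minrt <- stats$minrt
  pat <- .drift_pattern(stats)
  dims <- switch(m$family,
    ddm = {
      dd <- list(a = c(0.7, 1.3, 2, 3), snu = c(0.2, 1.0),
                 tau = c(0.3, 1.0, 2.0), w = c(0.3, 0.65),
                 lambda = c(0.2, 0.8), svis = c(0.3, 1.0),
                 sigvis = c(0.2, 0.8), t0 = c(0.5, 0.75, 0.9) * minrt,
                 D = c(0.5, 1, 2, 4))
      if (model %in% c("2DSD", "DDConf")) {
        dd$snu <- c(0.2, 0.6, 1.2)
        dd$z <- c(0.4, 0.5, 0.6)
        dd$sz <- c(0.05, 0.25)
        dd$st0 <- c(0.08, 0.25)
      }
      dd
    },
    race = {
      dd <- list(total = c(1.5, 2.5, 3.5), ratio = c(0.4, 0.5, 0.6),
                 t0 = c(0.5, 0.75, 0.9) * minrt, st0 = c(0.08, 0.25),
                 D = c(0.5, 1, 2, 4))
      if (m$time_dependent) dd$wcfg <- 1:4
      dd
    },
    mtlnr = list(t0 = c(0.5, 0.75, 0.9) * minrt, mdoff = c(-0.4, 0, 0.4),
                 s = c(0.25, 0.5, 1), rho = c(0, 0.5), st0 = c(0.08, 0.25),
                 D = c(0.25, 0.5, 1, 2)))
  # drop dimensions for parameters the model lacks or the user fixed
  keep <- setdiff(names(dims), names(fixed))
  if (m$family == "ddm") {
    keep <- setdiff(keep, setdiff(c("tau", "w", "lambda", "svis", "sigvis"),
                                  m$base))
    if (identical(restr_tau, "simult_conf") && "tau" %in% keep) {
      dims$tau <- pmin(dims$tau, 0.9 * pmax(minrt - min(dims$t0), 1e-2))
    }
  }
  dims <- dims[keep]
  grid <- expand.grid(dims, KEEP.OUT.ATTRS = FALSE)
  wcfgs <- list(c(0.9, 0.05), c(0.5, 0.25), c(1/3, 1/3), c(0.2, 0.6))
  lapply(seq_len(nrow(grid)), function(i) {
    g <- as.list(grid[i, , drop = FALSE])
    cand <- list()
    if (m$family == "race") {
      cand$A <- g$total * g$ratio
      cand$B <- g$total * (1 - g$ratio)
      if (m$time_dependent) {
        wc <- wcfgs[[g$wcfg]]
        cand$wX <- wc[1]; cand$wRT <- wc[2]; cand$wInt <- 1 - sum(wc)
      }
      cand$t0 <- g$t0
      cand$st0 <- if (!is.null(g$st0)) g$st0 else 0.15
      cand$d <- g$D * pat
    } else if (m$family == "ddm") {
      cand$a <- g$a
      cand$z <- if (!is.null(g$z)) g$z else 0.5
      cand$sz <- if (!is.null(g$sz)) g$sz else 0.1
      cand$snu <- g$snu
      cand$t0 <- g$t0
      cand$st0 <- if (!is.null(g$st0)) g$st0 else 0.15
      for (nm in c("tau", "w", "lambda", "svis", "sigvis")) {
        if (!is.null(g[[nm]])) cand[[nm]] <- g[[nm]]
      }
      cand$d <- g$D * pat
    } else {
      tdec <- max(as.numeric(stats$q50) - g$t0, 0.05)
      cand$d <- g$D * pat
      cand$mu_d1 <- cand$mu_d2 <- log(tdec) + g$mdoff + g$D * mean(pat)
      cand$s1 <- cand$s2 <- g$s
      cand$rho <- g$rho
      cand$t0 <- g$t0
      cand$st0 <- g$st0
    }
    # user-fixed values take precedence in the candidate
    for (nm in intersect(names(fixed), .get_model(model)$base)) {
      cand[[nm]] <- fixed[[nm]]
    }
    cand$simult_conf <- simult_conf
    cand$th <- lapply(stats$cum_props, function(cp)
      .anchor_thresholds(model, cand, stats, cp))
    cand
  })
}

#' Grid-search initialization for model fitting
#'
#' Evaluates the negative log-likelihood on a deterministic coarse product
#' grid over data-driven anchors (drift signs/scale from per-condition
#' accuracy, t0 below the minimum observed RT, thresholds at observed
#' rating proportions) and returns candidates ranked by NLL.
#'
#' @inheritParams fit_conf_model
#' @param n_return number of top candidates to return.
#' @return data frame of natural parameter rows with a \code{negLogLik}
#'   column, best first.
#' @export
initial_grid <- function(trials, model, fixed = list(), n_ratings = NULL,
                         simult_conf = FALSE, restr_tau = "none",
                         opts = list(), n_return = 50) {
  opts <- .default_opts(opts)
  K <- .get_K(trials, n_ratings)
  stats <- .data_stats(trials, K, isTRUE(fixed$sym_thetas))
  pm <- .make_par_map(model, fixed, stats, simult_conf, restr_tau)
  gr <- .grid_eval(trials, model, fixed, stats, pm, simult_conf, restr_tau,
                   opts)
  top <- head(order(gr$nll), n_return)
  rows <- lapply(top, function(i) {
    as.data.frame(pm$untransform(gr$x[[i]]))
  })
  out <- do.call(rbind, rows)
  out$negLogLik <- gr$nll[top]
  out
}

.grid_eval <- function(trials, model, fixed, stats, pm, simult_conf,
                       restr_tau, opts) {
  cands <- .grid_candidates(model, fixed, stats, simult_conf, restr_tau)
  if (length(cands) > opts$grid_size) {
    idx <- unique(round(seq(1, length(cands), length.out = opts$grid_size)))
    cands <- cands[idx]
  }
  xs <- lapply(cands, pm$transform)
  nll_fun <- .make_nll(trials, model, stats$K, opts$precision, simult_conf)
  nll <- vapply(xs, function(x) {
    v <- tryCatch(nll_fun(pm$untransform(x)), error = function(e) Inf)
    as.numeric(v)
  }, numeric(1))
  list(x = xs, nll = nll)
}

# -- fitting ----------------------------------------------------------------

#' Fit a confidence model to one subject's trials
#'
#' Maximum-likelihood estimation: grid-search initialization followed by
#' restarted Nelder-Mead optimization in a transformed, unconstrained
#' parameter space (log for positive parameters, logistic for interval
#' parameters, log-increments for ordered thresholds, stick-breaking for
#' the race confidence weights).  Unused extreme rating categories get
#' sentinel thresholds at \eqn{\mp\infty}; unused interior categories get
#' coincident thresholds; neither is optimized numerically.
#'
#' @param trials trial table for a single subject (see
#'   \code{\link{ingest_trials}}).
#' @param model one of \code{dynaViTE, dynWEV, 2DSD, DDConf, IRM, IRMt,
#'   PCRM, PCRMt, MTLNR}.
#' @param fixed named list of fixed parameters; may include
#'   \code{sym_thetas = TRUE} for response-symmetric thresholds.
#' @param n_ratings number of confidence categories K (recommended).
#' @param simult_conf choice and confidence reported simultaneously
#'   (response time then includes \code{tau}).
#' @param restr_tau \code{"none"}, \code{"simult_conf"} (bounds
#'   \code{t0 + tau} below the minimum observed RT), or a numeric upper
#'   bound for \code{tau}.
#' @param opts list overriding defaults \code{grid_size = 12000},
#'   \code{n_starts = 5}, \code{n_restarts = 5}, \code{max_evals = 5000},
#'   \code{precision = 3}.
#' @param seed optional seed.
#' @param subject optional subject identifier stored in the output row.
#' @return one-row data frame: fitted parameters, \code{N}, \code{k} (free
#'   parameters), \code{negLogLik}, \code{AIC}, \code{AICc}, \code{BIC},
#'   \code{fixed} (constraint record) and \code{wflag} (TRUE when the
#'   optimizer never improved on the best grid candidate).
#' @export
fit_conf_model <- function(trials, model, fixed = list(), n_ratings = NULL,
                           simult_conf = FALSE, restr_tau = "none",
                           opts = list(), seed = NULL, subject = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .get_model(model)
  if (model == "MTLNRfull")
    stop("MTLNRfull is not identifiable per subject; fit 'MTLNR'",
         call. = FALSE)
  bad <- setdiff(setdiff(names(fixed), "sym_thetas"), .get_model(model)$base)
  if (length(bad) > 0)
    stop("fixed parameter(s) not in model '", model, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  opts <- .default_opts(opts)
  K <- .get_K(trials, n_ratings)
  stats <- .data_stats(trials, K, isTRUE(fixed$sym_thetas))
  pm <- .make_par_map(model, fixed, stats, simult_conf, restr_tau)
  gr <- .grid_eval(trials, model, fixed, stats, pm, simult_conf, restr_tau,
                   opts)
  ord <- order(gr$nll)
  starts <- gr$x[ord[seq_len(min(opts$n_starts, length(ord)))]]
  nll_fun <- .make_nll(trials, model, stats$K, opts$precision, simult_conf)
  obj <- function(x) {
    v <- tryCatch(nll_fun(pm$untransform(x)), error = function(e) 1e10)
    as.numeric(v)
  }
  best_x <- starts[[1]]
  best_v <- gr$nll[ord[1]]
  improved <- FALSE
  for (x0 in starts) {
    x <- x0
    for (r in seq_len(opts$n_restarts)) {
      o <- optim(x, obj, method = "Nelder-Mead",
                 control = list(maxit = opts$max_evals, reltol = 1e-8))
      x <- o$par
      if (o$value < best_v - 1e-9) {
        best_v <- o$value; best_x <- x; improved <- TRUE
      }
    }
  }
  if (!improved)
    warning("optimizer never improved on the best grid candidate for ",
            model)
  par <- pm$untransform(best_x)
  N <- nrow(trials)
  k <- pm$k_free
  nll <- obj(best_x)
  row <- as.data.frame(par[!vapply(par, is.null, logical(1))])
  row <- cbind(
    data.frame(subject = if (!is.null(subject)) subject
               else trials$subject[1], model = model),
    row,
    data.frame(N = N, k = k, negLogLik = nll,
               AIC = 2 * nll + 2 * k,
               AICc = 2 * nll + 2 * k + 2 * k * (k + 1) / max(N - k - 1, 1),
               BIC = 2 * nll + k * log(N),
               fixed = .fixed_string(fixed), wflag = !improved))
  row
}

.fixed_string <- function(fixed) {
  if (length(fixed) == 0) return("")
  paste(vapply(names(fixed), function(nm)
    paste0(nm, "=", fixed[[nm]]), character(1)), collapse = ";")
}

.rbind_fill <- function(rows) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(NULL)
  all_nm <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (nm in setdiff(all_nm, names(r))) r[[nm]] <- NA
    r[all_nm]
  }))
}

#' Fit several models to several subjects
#'
#' Cross product of subjects and models, each fitted independently with
#' \code{\link{fit_conf_model}}.  Per-cell failures are recorded as rows
#' with \code{failed = TRUE} and do not affect other cells.  Parallel
#' execution (over cells) uses per-cell seeds derived from \code{seed}, so
#' serial and parallel runs give identical results.
#'
#' @inheritParams fit_conf_model
#' @param models character vector of model names.
#' @param parallel number of worker processes (1 = serial).
#' @return data frame with one row per subject x model.
#' @export
fit_conf_models <- function(trials, models, fixed = list(),
                            n_ratings = NULL, simult_conf = FALSE,
                            restr_tau = "none", opts = list(),
                            parallel = 1, seed = NULL) {
  for (mo in models) .get_model(mo)
  subj <- split_by_subject(trials)
  cells <- expand.grid(s = seq_along(subj), m = seq_along(models))
  run_cell <- function(i) {
    si <- cells$s[i]; mi <- cells$m[i]
    cell_seed <- if (!is.null(seed)) (seed + 7919L * i) %% 2147483587L
    tryCatch(
      fit_conf_model(subj[[si]], models[mi], fixed = fixed,
                     n_ratings = n_ratings, simult_conf = simult_conf,
                     restr_tau = restr_tau, opts = opts, seed = cell_seed,
                     subject = names(subj)[si]),
      error = function(e) data.frame(subject = names(subj)[si],
                                     model = models[mi],
                                     failed = TRUE,
                                     message = conditionMessage(e)))
  }
  rows <- if (parallel > 1) {
    parallel::mclapply(seq_len(nrow(cells)), run_cell,
                       mc.cores = parallel, mc.preschedule = FALSE)
  } else {
    lapply(seq_len(nrow(cells)), run_cell)
  }
  out <- .rbind_fill(rows)
  if (is.null(out$failed)) out$failed <- FALSE
  out$failed[is.na(out$failed)] <- FALSE
  rownames(out) <- NULL
  out
}
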