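# Trial-level simulation: low-level model simulators (explicit parameters)
# and a high-level simulator that consumes a fitted parameter row.

.rate_rating <- function(conf, response, th_lower, th_upper) {
  # rating = sum_k 1(c > theta_{R,k}) + 1
  out <- integer(length(conf))
  for (i in seq_along(conf)) {
    th <- if (response[i] > 0) th_upper else th_lower
    out[i] <- sum(conf[i] > th) + 1L
  }
  out
}

.draw_tnd <- function(n, t0, st0) {
  if (st0 > 0) runif(n, t0, t0 + st0) else rep(t0, n)
}

#' Simulate trials from the dynaViTE model
#'
#' Euler-Maruyama simulation (step \code{delta}) of the decision process
#' with a Brownian-bridge correction for within-step boundary crossings;
#' the post-decisional increment and the visibility evidence are drawn
#' exactly.  Trials that do not reach a boundary before \code{maxrt}
#' (decision time) get \code{response = 0} and missing rt/confidence.
#'
#' @inheritParams ddynaViTE
#' @param n number of trials.
#' @param delta discretization step in seconds.
#' @param maxrt maximal simulated decision time in seconds.
#' @param th_lower,th_upper optional ascending confidence thresholds (one
#'   per response sign) used to produce a discrete \code{rating}.
#' @param seed optional seed (applied via \code{set.seed}).
#' @return data frame with columns \code{response} (-1/0/+1), \code{t_dec},
#'   \code{rt}, \code{conf}, and \code{rating} when thresholds are given.
#' @export
rdynaViTE <- function(n, a, z, nu, sz = 0, snu = 0, tau = 0, w = 0.5,
                      lambda = 0, muv = abs(nu), sigvis = 0, svis = 1,
                      t0 = 0, st0 = 0, s = 1, delta = 0.001, maxrt = 15,
                      simult_conf = FALSE, th_lower = NULL, th_upper = NULL,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (maxrt <= t0) stop("maxrt must exceed t0", call. = FALSE)
  .check_ddm_pars(a, z, sz, snu, tau, w, lambda, svis, sigvis, t0, st0, s)
  m <- cpp_sim_dynaViTE(as.integer(n), a, z, sz, nu, snu, tau, muv, sigvis,
                        svis, w, lambda, s, delta, maxrt)
  out <- data.frame(response = as.integer(m[, 1]), t_dec = m[, 2],
                    conf = m[, 3])
  tnd <- .draw_tnd(n, t0, st0)
  out$rt <- out$t_dec + tnd + if (simult_conf) tau else 0
  out$rt[out$response == 0L] <- NA_real_
  if (!is.null(th_lower) || !is.null(th_upper)) {
    if (is.null(th_upper)) th_upper <- th_lower
    if (is.null(th_lower)) th_lower <- th_upper
    out$rating <- NA_integer_
    ok <- out$response != 0L
    out$rating[ok] <- .rate_rating(out$conf[ok], out$response[ok],
                                   th_lower, th_upper)
  }
  out[c("response", "t_dec", "rt", "conf",
        intersect("rating", names(out)))]
}

#' Simulate trials from a Wiener race model
#'
#' Correlated two-accumulator race simulated with step \code{delta} and
#' Brownian-bridge crossing corrections.  Responses are 1/2 (winning
#' accumulator), 0 when no boundary is hit before \code{maxrt}.
#'
#' @inheritParams dIRMt
#' @inheritParams rdynaViTE
#' @param rho noise correlation, 0 or -0.5.
#' @param time_dependent use the time-dependent confidence variable
#'   \eqn{c_{RMt}}; otherwise \eqn{c = b} (balance of evidence).
#' @return data frame with \code{response}, \code{t_dec}, \code{rt},
#'   \code{b} (loser's gap), \code{conf}, optional \code{rating}.
#' @export
rRM <- function(n, mu1, mu2, A, B, s1 = 1, s2 = 1, rho = 0,
                wX = 1, wRT = 0, wInt = 0, time_dependent = FALSE,
                t0 = 0, st0 = 0, delta = 0.001, maxrt = 15,
                th_lower = NULL, th_upper = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  .check_race_pars(A, B, s1, s2, rho, wX, wRT, wInt, t0, st0)
  m <- cpp_sim_race(as.integer(n), A, B, mu1, mu2, s1, s2, rho,
                    wX, wRT, wInt, time_dependent, delta, maxrt)
  out <- data.frame(response = as.integer(m[, 1]), t_dec = m[, 2],
                    b = m[, 3], conf = m[, 4])
  out$rt <- out$t_dec + .draw_tnd(n, t0, st0)
  out$rt[out$response == 0L] <- NA_real_
  if (!is.null(th_lower) || !is.null(th_upper)) {
    if (is.null(th_upper)) th_upper <- th_lower
    if (is.null(th_lower)) th_lower <- th_upper
    out$rating <- NA_integer_
    ok <- out$response != 0L
    # accumulator 1 plays the role of response +1
    rsign <- ifelse(out$response[ok] == 1L, 1L, -1L)
    out$rating[ok] <- .rate_rating(out$conf[ok], rsign, th_lower, th_upper)
  }
  out[c("response", "t_dec", "rt", "b", "conf",
        intersect("rating", names(out)))]
}

#' Simulate trials from the MTLNR model
#'
#' Exact sampling: boundary distances and rates are drawn from their
#' log-normal laws and crossing times computed as \eqn{T_i = D_i/V_i};
#' there is no discretization and no \code{response = 0}.
#'
#' @inheritParams dMTLNR
#' @inheritParams rdynaViTE
#' @return data frame with \code{response} (1/2), \code{t_dec}, \code{rt},
#'   \code{conf} (= log time ratio > 0), optional \code{rating}.
#' @export
rMTLNR <- function(n, mu_v1, mu_v2, mu_d1 = 0, mu_d2 = 0,
                   sigma_v1 = 1, sigma_v2 = 1, rho_v = 0,
                   sigma_d1 = 0, sigma_d2 = 0, rho_d = 0,
                   t0 = 0, st0 = 0, th_lower = NULL, th_upper = NULL,
                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  covd <- rho_d * sigma_d1 * sigma_d2
  covv <- rho_v * sigma_v1 * sigma_v2
  logd <- .rbvn(n, c(mu_d1, mu_d2), sigma_d1^2, sigma_d2^2, covd)
  logv <- .rbvn(n, c(mu_v1, mu_v2), sigma_v1^2, sigma_v2^2, covv)
  T1 <- exp(logd[, 1] - logv[, 1])
  T2 <- exp(logd[, 2] - logv[, 2])
  response <- ifelse(T1 <= T2, 1L, 2L)
  t_dec <- pmin(T1, T2)
  conf <- log(pmax(T1, T2) / t_dec)
  out <- data.frame(response = response, t_dec = t_dec, conf = conf)
  out$rt <- t_dec + .draw_tnd(n, t0, st0)
  if (!is.null(th_lower) || !is.null(th_upper)) {
    if (is.null(th_upper)) th_upper <- th_lower
    if (is.null(th_lower)) th_lower <- th_upper
    rsign <- ifelse(response == 1L, 1L, -1L)
    out$rating <- .rate_rating(conf, rsign, th_lower, th_upper)
  }
  out
}

# bivariate normal draws via Cholesky (allows zero variances)
.rbvn <- function(n, m, v1, v2, cv) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  s1 <- sqrt(v1)
  x1 <- m[1] + s1 * z1
  if (s1 > 0) {
    b <- cv / v1
    res <- v2 - cv^2 / v1
    x2 <- m[2] + b * s1 * z1 + sqrt(max(res, 0)) * z2
  } else {
    x2 <- m[2] + sqrt(v2) * z2
  }
  cbind(x1, x2)
}

#' Simulate an experiment from a fitted parameter row
#'
#' Simulates \code{n} trials per combination of stimulus identity and
#' difficulty condition using the drift mapping of the fitting layer in
#' reverse.  The number of conditions L is inferred from the \code{d1..dL}
#' entries of \code{fit_row}.
#'
#' @param fit_row one-row data frame or named list with a \code{model}
#'   entry and that model's fitted parameters (as produced by
#'   \code{\link{fit_conf_model}}).
#' @param n trials per stimulus x condition cell.
#' @param simult_conf add \code{tau} to the response time (simultaneous
#'   choice and confidence report).
#' @param aggregate return choice x rating counts instead of trials.
#' @param gamma also return Kruskal's gamma between confidence and
#'   accuracy (per condition) and between confidence and response time.
#' @param stimuli stimulus identities to simulate (default both).
#' @param delta,maxrt discretization settings for the path-based models.
#' @param seed optional seed.
#' @return data frame of trials (columns \code{stimulus},
#'   \code{condition}, \code{response}, \code{rt}, \code{conf},
#'   \code{rating}, \code{correct}), or aggregated counts; with
#'   \code{gamma}, a list with elements \code{simus} and \code{gamma}.
#' @export
simulate_fit_row <- function(fit_row, n = 100, simult_conf = FALSE,
                             aggregate = FALSE, gamma = FALSE,
                             stimuli = c(-1, 1), delta = 0.001, maxrt = 15,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- as.list(fit_row)
  model <- as.character(p$model)
  m <- .get_model(model)
  dnames <- grep("^d[0-9]+$", names(p), value = TRUE)
  L <- length(dnames)
  if (L == 0) stop("fit_row contains no drift entries d1..dL", call. = FALSE)
  d <- unlist(p[paste0("d", seq_len(L))])
  K <- .row_K(p)
  th <- .row_thresholds(p, K)
  pc <- .complete_params(p, model)
  res <- list()
  for (S in stimuli) for (l in seq_len(L)) {
    dr <- map_parameters(S, l, model, d)
    sim <- switch(m$family,
      ddm = rdynaViTE(n, a = pc$a, z = pc$z, nu = dr$nu, sz = pc$sz,
                      snu = pc$snu, tau = pc$tau, w = pc$w,
                      lambda = pc$lambda, muv = dr$muv, sigvis = pc$sigvis,
                      svis = pc$svis, t0 = pc$t0, st0 = pc$st0,
                      delta = delta, maxrt = maxrt,
                      simult_conf = simult_conf,
                      th_lower = th$lower, th_upper = th$upper),
      race = rRM(n, mu1 = dr$mu1, mu2 = dr$mu2, A = pc$A, B = pc$B,
                 rho = m$rho, wX = pc$wX, wRT = pc$wRT, wInt = pc$wInt,
                 time_dependent = m$time_dependent, t0 = pc$t0,
                 st0 = pc$st0, delta = delta, maxrt = maxrt,
                 th_lower = th$lower, th_upper = th$upper),
      mtlnr = rMTLNR(n, mu_v1 = dr$mu_v1, mu_v2 = dr$mu_v2,
                     mu_d1 = pc$mu_d1, mu_d2 = pc$mu_d2,
                     sigma_v1 = pc$s1, sigma_v2 = pc$s2, rho_v = pc$rho,
                     sigma_d1 = pc$sigma_d1, sigma_d2 = pc$sigma_d2,
                     rho_d = pc$rho_d, t0 = pc$t0, st0 = pc$st0,
                     th_lower = th$lower, th_upper = th$upper))
    resp <- sim$response
    if (m$family != "ddm") resp <- ifelse(resp == 0L, 0L,
                                          ifelse(resp == 1L, 1L, -1L))
    res[[length(res) + 1]] <- data.frame(
      stimulus = S, condition = l, response = resp, rt = sim$rt,
      conf = sim$conf, rating = sim$rating,
      correct = ifelse(resp == 0L, NA_integer_, as.integer(resp == S)))
  }
  simus <- do.call(rbind, res)
  out <- simus
  if (aggregate) {
    ok <- simus$response != 0L
    out <- as.data.frame(table(stimulus = simus$stimulus[ok],
                               condition = simus$condition[ok],
                               response = simus$response[ok],
                               rating = simus$rating[ok]),
                         responseName = "n")
  }
  if (gamma) {
    ok <- simus$response != 0L
    dropped <- sum(!ok)
    g_acc <- do.call(rbind, lapply(split(simus[ok, ], simus$condition[ok]),
      function(dd) data.frame(condition = dd$condition[1],
                              gamma = kruskal_gamma(dd$rating, dd$correct))))
    g_rt <- do.call(rbind, lapply(split(simus[ok, ], simus$condition[ok]),
      function(dd) data.frame(condition = dd$condition[1],
                              gamma = kruskal_gamma(dd$rating, rank(-dd$rt)))))
    return(list(simus = out,
                gamma = list(accuracy = g_acc, rt = g_rt,
                             n_dropped = dropped)))
  }
  out
}

#' Kruskal's gamma rank correlation
#'
#' \eqn{(C - D) / (C + D)} over concordant and discordant pairs; ties are
#' excluded from both counts.  Returns \code{NA} when all pairs are tied.
#'
#' @param x,y ordinal vectors of equal length (>= 2).
#' @return value in [-1, 1], or \code{NA}.
#' @export
kruskal_gamma <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ok <- !is.na(x) & !is.na(y)
  tab <- table(x[ok], y[ok])
  nr <- nrow(tab); nc <- ncol(tab)
  C <- D <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    n_ij <- tab[i, j]
    if (n_ij == 0) next
    if (i < nr && j < nc) C <- C + n_ij * sum(tab[(i + 1):nr, (j + 1):nc])
    if (i < nr && j > 1)  D <- D + n_ij * sum(tab[(i + 1):nr, 1:(j - 1)])
  }
  if (C + D == 0) return(NA_real_)
  (C - D) / (C + D)
}
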