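# Parameter-row utilities, condition-to-drift mapping, and the trial-level
# negative log-likelihood shared by fitting, prediction and recovery.

# fill a (possibly partial) named parameter list with model constraints and
# zero-defaults for absent optional entries
.complete_params <- function(p, model) {
  m <- .get_model(model)
  for (nm in names(m$constraints)) {
    if (is.null(p[[nm]]) || is.na(suppressWarnings(as.numeric(p[[nm]]))))
      p[[nm]] <- m$constraints[[nm]]
  }
  defaults <- switch(m$family,
    ddm = list(sz = 0, snu = 0, st0 = 0, t0 = 0, sigvis = 0, svis = 1,
               s = 1, lambda = 0, w = 1, tau = 0),
    race = list(st0 = 0, t0 = 0, s1 = 1, s2 = 1),
    mtlnr = list(st0 = 0, t0 = 0, sigma_d1 = 0, sigma_d2 = 0, rho_d = 0))
  for (nm in names(defaults)) if (is.null(p[[nm]]) ||
                                  is.na(suppressWarnings(as.numeric(p[[nm]]))))
    p[[nm]] <- defaults[[nm]]
  lapply(p, function(x) if (is.numeric(x)) as.numeric(x) else x)
}

# K implied by the threshold columns of a parameter row
.row_K <- function(p) {
  ths <- grep("^theta(Lower|Upper)?[0-9]+$", names(p), value = TRUE)
  k <- suppressWarnings(as.integer(sub("^theta(Lower|Upper)?", "", ths)))
  max(k) + 1L
}

# full K-1 threshold vectors per response sign from a parameter row;
# columns thetaLower1.. / thetaUpper1.., or theta1.. (symmetric)
.row_thresholds <- function(p, K) {
  get_vec <- function(prefix) {
    nm <- paste0(prefix, seq_len(K - 1))
    if (all(nm %in% names(p))) unlist(p[nm]) else NULL
  }
  lo <- get_vec("thetaLower")
  up <- get_vec("thetaUpper")
  if (is.null(lo) && is.null(up)) {
    sym <- get_vec("theta")
    if (is.null(sym)) stop("parameter row has no confidence thresholds",
                           call. = FALSE)
    lo <- up <- sym
  }
  if (is.null(lo)) lo <- up
  if (is.null(up)) up <- lo
  list(lower = unname(lo), upper = unname(up))
}

#' Map stimulus and condition to process drift rates
#'
#' Implements the drift mapping of the fitting layer: with stimulus
#' \eqn{S \in \{-1, +1\}} and discriminability parameter \eqn{d_l} of
#' condition \eqn{l}, the dynaViTE family uses \eqn{\nu = S d_l},
#' \eqn{\mu_V = d_l}; race models use \eqn{(\mu_1, \mu_2) =
#' (S d_l, -S d_l)}; MTLNR uses \eqn{(\mu_{v1}, \mu_{v2}) = (d_l, 0)} for
#' \eqn{S = +1} and \eqn{(0, d_l)} for \eqn{S = -1}.
#'
#' @param stimulus vector of stimulus identities (-1/+1).
#' @param condition vector of condition indices in 1..L.
#' @param model model name.
#' @param d vector of discriminability parameters, one per condition.
#' @return data frame of per-trial drift parameters (columns depend on the
#'   model family).
#' @export
map_parameters <- function(stimulus, condition, model, d) {
  m <- .get_model(model)
  l <- as.integer(condition)
  stopifnot(all(l >= 1), all(l <= length(d)))
  dl <- d[l]
  S <- as.numeric(stimulus)
  switch(m$family,
    ddm = data.frame(nu = S * dl, muv = dl),
    race = data.frame(mu1 = S * dl, mu2 = -S * dl),
    mtlnr = data.frame(mu_v1 = ifelse(S > 0, dl, 0),
                       mu_v2 = ifelse(S > 0, 0, dl)))
}

# joint density for each trial of a table given a full parameter row
.trial_density <- function(par_row, model, trials, precision = 3,
                           simult_conf = FALSE) {
  p <- .complete_params(as.list(par_row), model)
  m <- .get_model(model)
  K <- .get_K(trials)
  th <- .row_thresholds(p, K)
  full_lo <- c(-Inf, th$lower, Inf)
  full_up <- c(-Inf, th$upper, Inf)
  r <- trials$rating
  up_sel <- trials$response > 0
  th1 <- ifelse(up_sel, full_up[r], full_lo[r])
  th2 <- ifelse(up_sel, full_up[r + 1], full_lo[r + 1])
  dnames <- paste0("d", seq_along(grep("^d[0-9]+$", names(p))))
  d <- unlist(p[dnames])
  dr <- map_parameters(trials$stimulus, as.integer(trials$condition),
                       model, d)
  if (m$family == "ddm") {
    .d_ddm_family(trials$rt, trials$response, th1, th2, dr$nu, dr$muv,
                  p$a, p$z, p$sz, p$snu, p$tau, p$w, p$lambda, p$svis,
                  p$sigvis, p$t0, p$st0, p$s, precision, simult_conf)
  } else if (m$family == "race") {
    resp12 <- ifelse(trials$response > 0, 1L, 2L)
    th1r <- pmax(th1, 0)  # race confidence is nonnegative
    .d_race(trials$rt, resp12, th1r, th2, dr$mu1, dr$mu2, p$A, p$B,
            p$s1, p$s2, m$rho, p$wX, p$wRT, p$wInt, p$t0, p$st0,
            m$time_dependent, precision)
  } else {
    resp12 <- ifelse(trials$response > 0, 1L, 2L)
    th1r <- pmax(th1, 0)
    dMTLNR(trials$rt, resp12, th1r, th2, dr$mu_v1, dr$mu_v2,
           p$mu_d1, p$mu_d2, p$s1, p$s2, p$rho,
           p$sigma_d1, p$sigma_d2, p$rho_d, p$t0, p$st0, precision)
  }
}

#' Negative log-likelihood of a parameter set
#'
#' \eqn{-\sum_i \log P(rt_i, C_i, R_i | \vartheta, S_i, l_i)} under
#' independent trials.  Trials with zero density contribute a large finite
#' penalty (\code{-log(1e-300)} each) so optimizers can recover; their
#' count is attached as attribute \code{n_zero}.
#'
#' @param par_row named list / one-row data frame with the model's natural
#'   parameters, drifts \code{d1..dL} and thresholds
#'   (\code{thetaLower*}/\code{thetaUpper*} or \code{theta*}).
#' @param trials trial table (see \code{\link{ingest_trials}}).
#' @param model model name.
#' @param precision density precision (default 3, the fitting default).
#' @param simult_conf simultaneous choice/confidence report.
#' @return non-negative scalar with attribute \code{n_zero}.
#' @export
neg_loglik <- function(par_row, trials, model, precision = 3,
                       simult_conf = FALSE) {
  dens <- .trial_density(par_row, model, trials, precision, simult_conf)
  n_zero <- sum(dens < 1e-300)
  val <- -sum(log(pmax(dens, 1e-300)))
  attr(val, "n_zero") <- n_zero
  val
}

# Fast NLL closure for optimization: per-trial structures are precomputed
# once, so each evaluation only maps parameters and calls the C++ kernel.
.make_nll <- function(trials, model, K, precision, simult_conf) {
  m <- .get_model(model)
  S <- as.numeric(trials$stimulus)
  l <- as.integer(trials$condition)
  rt <- as.numeric(trials$rt)
  rating <- as.integer(trials$rating)
  up_sel <- trials$response > 0
  resp_pm <- as.integer(trials$response)
  resp_12 <- ifelse(up_sel, 1L, 2L)
  lo_idx <- rating       # into c(-Inf, theta, Inf)
  hi_idx <- rating + 1L
  L <- nlevels(trials$condition)
  dn <- paste0("d", seq_len(L))
  thl_nm <- paste0("thetaLower", seq_len(K - 1))
  thu_nm <- paste0("thetaUpper", seq_len(K - 1))
  th_nm <- paste0("theta", seq_len(K - 1))
  function(p) {
    if (!is.null(p[[thl_nm[1]]])) {
      thL <- c(-Inf, unlist(p[thl_nm], use.names = FALSE), Inf)
      thU <- c(-Inf, unlist(p[thu_nm], use.names = FALSE), Inf)
    } else {
      thL <- thU <- c(-Inf, unlist(p[th_nm], use.names = FALSE), Inf)
    }
    th1 <- ifelse(up_sel, thU[lo_idx], thL[lo_idx])
    th2 <- ifelse(up_sel, thU[hi_idx], thL[hi_idx])
    d <- unlist(p[dn], use.names = FALSE)
    dl <- d[l]
    dens <- if (m$family == "ddm") {
      cpp_ddm_conf(rt, resp_pm, th1, th2, S * dl, dl,
                   p$a, p$z, p$sz, p$snu, p$tau, p$w, p$lambda,
                   p$svis, p$sigvis, p$t0, p$st0, p$s, precision,
                   simult_conf)
    } else if (m$family == "race") {
      cpp_race_conf(rt, resp_12, pmax(th1, 0), th2, S * dl, -S * dl,
                    p$A, p$B, p$s1, p$s2, m$rho, p$wX, p$wRT, p$wInt,
                    p$t0, p$st0, m$time_dependent, precision)
    } else {
      cpp_mtlnr_conf(rt, resp_12, pmax(th1, 0), th2,
                     ifelse(S > 0, dl, 0), ifelse(S > 0, 0, dl),
                     p$mu_d1, p$mu_d2, p$sigma_d1, p$sigma_d2, p$rho_d,
                     p$s1, p$s2, p$rho, p$t0, p$st0, precision)
    }
    -sum(log(pmax(dens, 1e-300)))
  }
}
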