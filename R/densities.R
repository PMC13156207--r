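# User-facing density functions.  All return the joint probability density
# P(rt, response, c in [th1, th2] | parameters): a defective RT density for
# the given response whose integral over rt equals the probability of that
# response and confidence bin.

.recycle <- function(n, ...) {
  lapply(list(...), function(x) {
    if (length(x) == 1) rep(x, n) else {
      if (length(x) != n) stop("argument lengths differ", call. = FALSE)
      x
    }
  })
}

.check_ddm_pars <- function(a, z, sz, snu, tau, w, lambda, svis, sigvis,
                            t0, st0, s) {
  if (a <= 0) stop("invalid parameters: a must be > 0", call. = FALSE)
  if (s <= 0) stop("invalid parameters: s must be > 0", call. = FALSE)
  if (z <= 0 || z >= 1) stop("invalid parameters: z must be in (0,1)", call. = FALSE)
  if (sz < 0 || z - sz / 2 <= 0 || z + sz / 2 >= 1)
    stop("invalid parameters: start distribution z +/- sz/2 outside (0,1)",
         call. = FALSE)
  if (snu < 0) stop("invalid parameters: snu must be >= 0", call. = FALSE)
  if (tau < 0) stop("invalid parameters: tau must be >= 0", call. = FALSE)
  if (w < 0 || w > 1) stop("invalid parameters: w must be in [0,1]", call. = FALSE)
  if (lambda < 0) stop("invalid parameters: lambda must be >= 0", call. = FALSE)
  if (svis <= 0 && w < 1)
    stop("invalid parameters: svis must be > 0", call. = FALSE)
  if (sigvis < 0) stop("invalid parameters: sigvis must be >= 0", call. = FALSE)
  if (t0 < 0 || st0 < 0)
    stop("invalid parameters: t0 and st0 must be >= 0", call. = FALSE)
  invisible(TRUE)
}

.check_th <- function(th1, th2) {
  if (any(th1 > th2)) stop("th1 must be <= th2", call. = FALSE)
}

#' First-passage time density of the drift-diffusion decision process
#'
#' Defective density of the decision time at the boundary selected by
#' \code{response} (+1 upper, -1 lower), marginal over the normal drift
#' distribution (mean \code{nu}, SD \code{snu}; closed form) and the
#' uniform starting point (relative mean \code{z}, range \code{sz};
#' midpoint rule with step count controlled by \code{precision}).
#'
#' @param t decision time(s) in seconds; non-positive values give 0.
#' @param response +1 (upper boundary) or -1 (lower boundary).
#' @param a boundary separation. @param z mean relative starting point.
#' @param sz range of the uniform starting-point distribution.
#' @param nu mean drift rate. @param snu across-trial drift SD.
#' @param s diffusion constant.
#' @param precision number of digits of the density that are correct on
#'   average (default 6).
#' @return vector of non-negative densities.
#' @export
dfpt_ddm <- function(t, response, a, z, sz = 0, nu = 0, snu = 0, s = 1,
                     precision = 6) {
  .check_ddm_pars(a, z, sz, snu, 0, 1, 0, 1, 0, 0, 0, s)
  stopifnot(response %in% c(-1, 1), length(response) == 1)
  cpp_fpt_ddm(as.numeric(t), as.integer(response), a, z, sz, nu, snu, s,
              precision)
}

# shared backend for the dynaViTE family
.d_ddm_family <- function(rt, response, th1, th2, nu, muv, a, z, sz, snu,
                          tau, w, lambda, svis, sigvis, t0, st0, s,
                          precision, simult_conf) {
  .check_ddm_pars(a, z, sz, snu, tau, w, lambda, svis, sigvis, t0, st0, s)
  .check_th(th1, th2)
  n <- max(length(rt), length(response), length(th1), length(th2),
           length(nu), length(muv))
  v <- .recycle(n, rt, response, th1, th2, nu, muv)
  cpp_ddm_conf(as.numeric(v[[1]]), as.integer(v[[2]]), as.numeric(v[[3]]),
               as.numeric(v[[4]]), as.numeric(v[[5]]), as.numeric(v[[6]]),
               a, z, sz, snu, tau, w, lambda, svis, sigvis, t0, st0, s,
               precision, simult_conf)
}

#' Joint density for the dynaViTE model
#'
#' Density of observing response time \code{rt} and response
#' \code{response}, jointly with the internal confidence variable
#' \deqn{c = [w R (X(T+\tau) - a z) + (1-w) V(T+\tau)] / (T+\tau)^\lambda}
#' falling in \code{[th1, th2]}.  \code{rt} is decision time plus
#' non-decision time, plus \code{tau} when \code{simult_conf}.
#'
#' @param rt observed response time(s), seconds.
#' @param response +1 or -1 (boundary reached).
#' @param th1,th2 confidence interval bounds (\code{-Inf}/\code{Inf}
#'   allowed); \code{th1 <= th2}.
#' @param a,z,sz,nu,snu,s decision-process parameters (see
#'   \code{\link{dfpt_ddm}}).
#' @param tau post-decisional accumulation period, seconds.
#' @param w weight on decision evidence (vs. visibility evidence).
#' @param lambda exponent of accumulation time in the confidence variable.
#' @param muv mean visibility drift. @param sigvis across-trial SD of the
#'   visibility drift. @param svis diffusion constant of the visibility
#'   process.
#' @param t0 minimal non-decision time. @param st0 range of the uniform
#'   non-decision time.
#' @param precision average number of correct digits (default 6).
#' @param simult_conf were choice and confidence reported simultaneously?
#'   If so, \code{tau} is part of the observed response time.
#' @return vector of non-negative joint densities.
#' @export
ddynaViTE <- function(rt, response, th1, th2, a, z, nu, sz = 0, snu = 0,
                      tau = 0, w = 0.5, lambda = 0, muv = abs(nu),
                      sigvis = 0, svis = 1, t0 = 0, st0 = 0, s = 1,
                      precision = 6, simult_conf = FALSE) {
  .d_ddm_family(rt, response, th1, th2, nu, muv, a, z, sz, snu, tau, w,
                lambda, svis, sigvis, t0, st0, s, precision, simult_conf)
}

#' @rdname ddynaViTE
#' @details \code{ddynWEV} is dynaViTE without time penalization
#'   (\code{lambda = 0}).
#' @export
ddynWEV <- function(rt, response, th1, th2, a, z, nu, sz = 0, snu = 0,
                    tau = 0, w = 0.5, muv = abs(nu), sigvis = 0, svis = 1,
                    t0 = 0, st0 = 0, s = 1, precision = 6,
                    simult_conf = FALSE) {
  .d_ddm_family(rt, response, th1, th2, nu, muv, a, z, sz, snu, tau, w,
                0, svis, sigvis, t0, st0, s, precision, simult_conf)
}

#' @rdname ddynaViTE
#' @details \code{d2DSD} sets \code{lambda = 0, w = 1}: confidence is the
#'   post-decisionally accumulated decision evidence only; the visibility
#'   process is ignored.
#' @export
d2DSD <- function(rt, response, th1, th2, a, z, nu, sz = 0, snu = 0,
                  tau = 0, t0 = 0, st0 = 0, s = 1, precision = 6,
                  simult_conf = FALSE) {
  .d_ddm_family(rt, response, th1, th2, nu, 0, a, z, sz, snu, tau, 1,
                0, 1, 0, t0, st0, s, precision, simult_conf)
}

#' @rdname ddynaViTE
#' @details \code{dDDConf} sets \code{w = 1, tau = 0, lambda = 0.5}:
#'   confidence is a decreasing function of decision time (thresholds live
#'   on the \eqn{a\zeta_R/\sqrt{T}} scale, a response-specific positive
#'   rescaling of \eqn{1/\sqrt{T}}).
#' @export
dDDConf <- function(rt, response, th1, th2, a, z, nu, sz = 0, snu = 0,
                    t0 = 0, st0 = 0, s = 1, precision = 6) {
  .d_ddm_family(rt, response, th1, th2, nu, 0, a, z, sz, snu, 0, 1,
                0.5, 1, 0, t0, st0, s, precision, FALSE)
}

.check_race_pars <- function(A, B, s1, s2, rho, wX, wRT, wInt, t0, st0) {
  if (A <= 0 || B <= 0) stop("invalid parameters: thresholds A, B must be > 0",
                             call. = FALSE)
  if (s1 <= 0 || s2 <= 0) stop("invalid parameters: s1, s2 must be > 0",
                               call. = FALSE)
  if (!rho %in% c(0, -0.5))
    stop("rho must be exactly 0 (IRM) or -0.5 (PCRM)", call. = FALSE)
  if (wX < 0 || wRT < 0 || wInt < 0 || abs(wX + wRT + wInt - 1) > 1e-8)
    stop("invalid parameters: confidence weights must be >= 0 and sum to 1",
         call. = FALSE)
  if (t0 < 0 || st0 < 0) stop("invalid parameters: t0, st0 must be >= 0",
                              call. = FALSE)
  invisible(TRUE)
}

#' First-passage density of the two-accumulator Wiener race
#'
#' Closed-form (method of images) joint density of decision time \code{t},
#' winning accumulator \code{winner}, and the losing accumulator's distance
#' \code{b} to its own threshold.
#'
#' @param t decision time(s). @param winner 1 or 2. @param b gap >= 0.
#' @param A,B upper thresholds. @param mu1,mu2 drifts.
#' @param s1,s2 diffusion constants. @param rho correlation, 0 or -0.5.
#' @return vector of non-negative densities (per time and gap unit).
#' @export
dfpt_race <- function(t, winner, b, A, B, mu1, mu2, s1 = 1, s2 = 1,
                      rho = 0) {
  .check_race_pars(A, B, s1, s2, rho, 1, 0, 0, 0, 0)
  n <- max(length(t), length(winner), length(b))
  v <- .recycle(n, t, winner, b)
  cpp_fpt_race(as.numeric(v[[1]]), as.integer(v[[2]]), as.numeric(v[[3]]),
               A, B, mu1, mu2, s1, s2, rho)
}

# shared backend for race models
.d_race <- function(rt, response, th1, th2, mu1, mu2, A, B, s1, s2, rho,
                    wX, wRT, wInt, t0, st0, time_dependent, precision) {
  .check_race_pars(A, B, s1, s2, rho, wX, wRT, wInt, t0, st0)
  .check_th(th1, th2)
  n <- max(length(rt), length(response), length(th1), length(th2),
           length(mu1), length(mu2))
  v <- .recycle(n, rt, response, th1, th2, mu1, mu2)
  cpp_race_conf(as.numeric(v[[1]]), as.integer(v[[2]]), as.numeric(v[[3]]),
                as.numeric(v[[4]]), as.numeric(v[[5]]), as.numeric(v[[6]]),
                A, B, s1, s2, rho, wX, wRT, wInt, t0, st0, time_dependent,
                precision)
}

#' Joint density for Wiener race models of confidence
#'
#' Density of (rt, response, confidence in [th1, th2]) for the
#' time-dependent race models IRMt (\code{rho = 0}) and PCRMt
#' (\code{rho = -0.5}), with confidence variable
#' \deqn{c = w_X b + w_{RT}/\sqrt{T} + w_{Int}\, b/\sqrt{T},}
#' where b is the losing accumulator's distance to its threshold (balance
#' of evidence).  \code{dIRM}/\code{dPCRM} use the time-independent special
#' case \eqn{c = b} (weights (1,0,0)).
#'
#' @param rt response time(s). @param response 1 or 2 (winning
#'   accumulator).
#' @param th1,th2 confidence interval; \code{th1 <= th2}.
#' @param mu1,mu2 accumulator drifts. @param A,B thresholds.
#' @param s1,s2 diffusion constants. @param wX,wRT,wInt confidence weights
#'   (>= 0, summing to 1).
#' @param t0,st0 non-decision time parameters.
#' @param precision average number of correct digits (default 6).
#' @return vector of non-negative joint densities.
#' @export
dIRMt <- function(rt, response, th1, th2, mu1, mu2, A, B, s1 = 1, s2 = 1,
                  wX = 1/3, wRT = 1/3, wInt = 1/3, t0 = 0, st0 = 0,
                  precision = 6) {
  .d_race(rt, response, th1, th2, mu1, mu2, A, B, s1, s2, 0,
          wX, wRT, wInt, t0, st0, TRUE, precision)
}

#' @rdname dIRMt
#' @export
dPCRMt <- function(rt, response, th1, th2, mu1, mu2, A, B, s1 = 1, s2 = 1,
                   wX = 1/3, wRT = 1/3, wInt = 1/3, t0 = 0, st0 = 0,
                   precision = 6) {
  .d_race(rt, response, th1, th2, mu1, mu2, A, B, s1, s2, -0.5,
          wX, wRT, wInt, t0, st0, TRUE, precision)
}

#' @rdname dIRMt
#' @export
dIRM <- function(rt, response, th1, th2, mu1, mu2, A, B, s1 = 1, s2 = 1,
                 t0 = 0, st0 = 0, precision = 6) {
  .d_race(rt, response, th1, th2, mu1, mu2, A, B, s1, s2, 0,
          1, 0, 0, t0, st0, FALSE, precision)
}

#' @rdname dIRMt
#' @export
dPCRM <- function(rt, response, th1, th2, mu1, mu2, A, B, s1 = 1, s2 = 1,
                  t0 = 0, st0 = 0, precision = 6) {
  .d_race(rt, response, th1, th2, mu1, mu2, A, B, s1, s2, -0.5,
          1, 0, 0, t0, st0, FALSE, precision)
}

#' Joint density for the multiple-threshold log-normal race model
#'
#' Boundary crossing times are \eqn{T_i = D_i / V_i} with log-normal
#' boundary distances and accumulation rates, so the log crossing times are
#' bivariate normal.  Confidence is \eqn{c = \log(T_{lose}/T_{win}) \ge 0};
#' \code{th1 >= 0} is required.
#'
#' @param rt response time(s). @param response 1 or 2 (winner).
#' @param th1,th2 confidence interval, \code{0 <= th1 <= th2}.
#' @param mu_v1,mu_v2 mean log accumulation rates.
#' @param mu_d1,mu_d2 mean log boundary distances.
#' @param sigma_v1,sigma_v2,rho_v SDs and correlation of the log rates.
#' @param sigma_d1,sigma_d2,rho_d SDs and correlation of the log boundary
#'   distances (fixed to 0 in the per-subject fitting configuration).
#' @param t0,st0 non-decision time parameters.
#' @param precision average number of correct digits (default 6).
#' @return vector of non-negative joint densities.
#' @export
dMTLNR <- function(rt, response, th1, th2, mu_v1, mu_v2,
                   mu_d1 = 0, mu_d2 = 0, sigma_v1 = 1, sigma_v2 = 1,
                   rho_v = 0, sigma_d1 = 0, sigma_d2 = 0, rho_d = 0,
                   t0 = 0, st0 = 0, precision = 6) {
  if (any(th1 < 0, na.rm = TRUE))
    stop("th1 must be >= 0 (the log time ratio is positive)", call. = FALSE)
  .check_th(th1, th2)
  if (sigma_v1 < 0 || sigma_v2 < 0 || sigma_d1 < 0 || sigma_d2 < 0)
    stop("invalid parameters: variance parameters must be >= 0", call. = FALSE)
  if (abs(rho_v) > 1 || abs(rho_d) > 1)
    stop("invalid parameters: correlations must be in [-1, 1]", call. = FALSE)
  if (sigma_d1^2 + sigma_v1^2 <= 0 || sigma_d2^2 + sigma_v2^2 <= 0)
    stop("invalid parameters: each log crossing time needs positive variance",
         call. = FALSE)
  if (t0 < 0 || st0 < 0) stop("invalid parameters: t0, st0 must be >= 0",
                              call. = FALSE)
  n <- max(length(rt), length(response), length(th1), length(th2),
           length(mu_v1), length(mu_v2))
  v <- .recycle(n, rt, response, th1, th2, mu_v1, mu_v2)
  cpp_mtlnr_conf(as.numeric(v[[1]]), as.integer(v[[2]]), as.numeric(v[[3]]),
                 as.numeric(v[[4]]), as.numeric(v[[5]]), as.numeric(v[[6]]),
                 mu_d1, mu_d2, sigma_d1, sigma_d2, rho_d,
                 sigma_v1, sigma_v2, rho_v, t0, st0, precision)
}
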