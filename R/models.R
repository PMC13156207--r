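# Model registry: parameter lists and structural constants for every
# supported model.  Base parameters exclude the condition-wise drift
# parameters d1..dL and the confidence thresholds.

.models <- list(
  dynaViTE = list(
    family = "ddm",
    base = c("a", "z", "sz", "snu", "tau", "w", "lambda", "svis", "sigvis",
             "t0", "st0"),
    constraints = list()),
  dynWEV = list(
    family = "ddm",
    base = c("a", "z", "sz", "snu", "tau", "w", "svis", "sigvis",
             "t0", "st0"),
    constraints = list(lambda = 0)),
  `2DSD` = list(
    family = "ddm",
    base = c("a", "z", "sz", "snu", "tau", "t0", "st0"),
    constraints = list(lambda = 0, w = 1, svis = 1, sigvis = 0)),
  DDConf = list(
    family = "ddm",
    base = c("a", "z", "sz", "snu", "t0", "st0"),
    constraints = list(lambda = 0.5, w = 1, tau = 0, svis = 1, sigvis = 0)),
  IRM = list(
    family = "race", rho = 0, time_dependent = FALSE,
    base = c("A", "B", "t0", "st0"),
    constraints = list(wX = 1, wRT = 0, wInt = 0)),
  IRMt = list(
    family = "race", rho = 0, time_dependent = TRUE,
    base = c("A", "B", "wX", "wRT", "t0", "st0"),
    constraints = list()),
  PCRM = list(
    family = "race", rho = -0.5, time_dependent = FALSE,
    base = c("A", "B", "t0", "st0"),
    constraints = list(wX = 1, wRT = 0, wInt = 0)),
  PCRMt = list(
    family = "race", rho = -0.5, time_dependent = TRUE,
    base = c("A", "B", "wX", "wRT", "t0", "st0"),
    constraints = list()),
  MTLNR = list(
    family = "mtlnr",
    base = c("mu_d1", "mu_d2", "s1", "s2", "rho", "t0", "st0"),
    constraints = list(sigma_d1 = 0, sigma_d2 = 0, rho_d = 0)),
  # full parameterization of the density layer (not fittable per subject:
  # not identifiable; used in the precision benchmark)
  MTLNRfull = list(
    family = "mtlnr",
    base = c("mu_d1", "mu_d2", "sigma_d1", "sigma_d2", "rho_d",
             "s1", "s2", "rho", "t0", "st0"),
    constraints = list())
)

.model_names <- function(fittable_only = FALSE) {
  nm <- names(.models)
  if (fittable_only) nm <- setdiff(nm, "MTLNRfull")
  nm
}

.get_model <- function(model) {
  m <- .models[[model]]
  if (is.null(m)) {
    stop("unknown model '", model, "'; supported models: ",
         paste(names(.models), collapse = ", "), call. = FALSE)
  }
  m
}

#' Number of free parameters of a confidence model
#'
#' Returns the number of parameters estimated when fitting \code{model} with
#' \code{L} difficulty conditions and a \code{K}-point confidence scale:
#' base parameters + \code{L} condition drifts + \code{2(K-1)}
#' response-specific confidence thresholds (one set of \code{K-1} when
#' \code{sym_thetas}), minus user-fixed parameters.
#'
#' For the precision-benchmark configuration (L = 3, K = 3) this yields 18
#' for dynaViTE, 13 for IRMt/PCRMt, and 17 for the full MTLNR
#' parameterization (\code{"MTLNRfull"}).
#'
#' @param model model name (e.g. \code{"dynaViTE"}, \code{"IRMt"},
#'   \code{"MTLNR"}, \code{"MTLNRfull"}).
#' @param L number of difficulty conditions (>= 1).
#' @param K number of confidence categories (>= 2).
#' @param fixed named list of user-fixed parameters (may contain
#'   \code{sym_thetas}); fixed names not present in the model are ignored.
#' @param sym_thetas logical; shared thresholds for the two responses.
#' @return integer count of free parameters.
#' @export
count_free_parameters <- function(model, L, K, fixed = list(),
                                  sym_thetas = FALSE) {
  m <- .get_model(model)
  stopifnot(L >= 1, K >= 2)
  if (isTRUE(fixed$sym_thetas)) sym_thetas <- TRUE
  fixed_names <- setdiff(names(fixed), "sym_thetas")
  n_theta <- if (sym_thetas) (K - 1) else 2 * (K - 1)
  n_fixed <- sum(fixed_names %in% m$base)
  as.integer(length(m$base) + L + n_theta - n_fixed)
}
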