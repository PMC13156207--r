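# Subject-level information-criterion weights and group-level random
# effects Bayesian model selection (variational Bayes over a Dirichlet
# population model; exceedance, protected exceedance probabilities and the
# Bayesian omnibus risk).

.ic_matrix <- function(fits, measure) {
  fits <- as.data.frame(fits)
  if (!measure %in% names(fits))
    stop("measure column '", measure, "' not found", call. = FALSE)
  subs <- unique(fits$subject)
  mods <- unique(fits$model)
  M <- matrix(NA_real_, length(subs), length(mods),
              dimnames = list(as.character(subs), mods))
  for (i in seq_len(nrow(fits))) {
    M[as.character(fits$subject[i]), fits$model[i]] <- fits[[measure]][i]
  }
  if (any(is.na(M))) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop("missing ", measure, " for subject ", rownames(M)[bad[1]],
         ", model ", colnames(M)[bad[2]], call. = FALSE)
  }
  M
}

#' Subject-level model weights from information criteria
#'
#' Per subject, \eqn{w_m = \exp(-\Delta_m/2) / \sum_j \exp(-\Delta_j/2)}
#' with \eqn{\Delta_m = IC_m - \min_j IC_j}.
#'
#' @param fits fit table with columns \code{subject}, \code{model} and the
#'   chosen information criterion; every subject needs a row for every
#'   model.
#' @param measure \code{"BIC"} (default), \code{"AIC"} or \code{"AICc"}.
#' @return data frame: \code{subject} plus one weight column per model.
#' @export
subject_modelweights <- function(fits, measure = "BIC") {
  M <- .ic_matrix(fits, measure)
  W <- t(apply(M, 1, function(ic) {
    d <- ic - min(ic)
    w <- exp(-d / 2)
    w / sum(w)
  }))
  out <- data.frame(subject = rownames(M), W, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Group-level Bayesian model selection
#'
#' Random-effects model selection across subjects: log model evidence is
#' approximated as \eqn{-IC/2}; a Dirichlet distribution over population
#' model frequencies is estimated by variational Bayes (Dirichlet prior
#' \code{alpha0} = 1 per model).  Reports posterior mean model
#' frequencies, exceedance probabilities (EP; analytic Beta comparison for
#' two models, Monte-Carlo Dirichlet sampling otherwise), the Bayesian
#' omnibus risk (BOR; variational free-energy comparison of the random
#' effects model against the equal-frequency null) and protected
#' exceedance probabilities \eqn{PEP = (1-BOR)\,EP + BOR/M}.  Fixed-effects
#' model probabilities (weights of the summed IC) are also returned.
#'
#' @inheritParams subject_modelweights
#' @param mc_samples Dirichlet samples for EP when more than two models.
#' @param alpha0 prior Dirichlet mass per model.
#' @param tol convergence tolerance on the alpha update.
#' @param max_iter iteration cap for the variational updates.
#' @param seed optional seed for the Monte-Carlo EP.
#' @return list with \code{alpha}, \code{model_probs}, \code{ep},
#'   \code{pep}, \code{bor}, \code{fixed_effect_probs}, and diagnostics
#'   \code{iterations} and \code{free_energy} (trace, non-decreasing).
#' @export
group_BMS_fit <- function(fits, measure = "BIC", mc_samples = 1e6,
                          alpha0 = 1, tol = 1e-8, max_iter = 500,
                          seed = NULL) {
  IC <- .ic_matrix(fits, measure)
  lme <- -IC / 2
  n <- nrow(lme); M <- ncol(lme)
  alpha <- rep(alpha0, M)
  Ftrace <- numeric(0)
  z <- matrix(1 / M, n, M)
  for (it in seq_len(max_iter)) {
    e <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    e <- e - apply(e, 1, max)
    z <- exp(e) / rowSums(exp(e))
    alpha_new <- alpha0 + colSums(z)
    Ftrace <- c(Ftrace, .bms_free_energy(lme, z, alpha_new, alpha0))
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
    if (it == max_iter)
      stop("variational updates did not converge within ", max_iter,
           " iterations", call. = FALSE)
  }
  ep <- .exceedance(alpha, mc_samples, seed)
  F1 <- Ftrace[length(Ftrace)]
  F0 <- sum(apply(lme, 1, function(l) {
    mx <- max(l); mx + log(mean(exp(l - mx)))
  }))
  bor <- 1 / (1 + exp(F1 - F0))
  pep <- (1 - bor) * ep + bor / M
  sums <- colSums(IC)
  d <- sums - min(sums)
  fixed <- exp(-d / 2) / sum(exp(-d / 2))
  list(alpha = setNames(alpha, colnames(lme)),
       model_probs = setNames(alpha / sum(alpha), colnames(lme)),
       ep = setNames(ep, colnames(lme)),
       pep = setNames(pep, colnames(lme)),
       bor = bor,
       fixed_effect_probs = setNames(fixed, colnames(lme)),
       iterations = length(Ftrace), free_energy = Ftrace)
}

# variational free energy of the random-effects model
.bms_free_energy <- function(lme, z, alpha, alpha0) {
  M <- ncol(lme)
  a0 <- rep(alpha0, M)
  psi <- digamma(alpha) - digamma(sum(alpha))
  Elogp_y <- sum(z * lme)
  Elogp_z <- sum(z %*% psi)
  Elogp_r <- lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * psi)
  Hq_z <- -sum(z[z > 0] * log(z[z > 0]))
  Hq_r <- -(lgamma(sum(alpha)) - sum(lgamma(alpha)) +
              sum((alpha - 1) * psi))
  Elogp_y + Elogp_z + Elogp_r + Hq_z + Hq_r
}

.exceedance <- function(alpha, mc_samples, seed = NULL) {
  M <- length(alpha)
  if (M == 2) {
    # P(x1 > x2) = P(Beta(a1, a2) > 1/2)
    return(c(1 - pbeta(0.5, alpha[1], alpha[2]),
             pbeta(0.5, alpha[1], alpha[2])))
  }
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(rgamma(mc_samples * M, shape = rep(alpha, each = mc_samples)),
              mc_samples, M)
  win <- max.col(g, ties.method = "first")
  as.numeric(tabulate(win, M)) / mc_samples
}
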