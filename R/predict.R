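# Predicted outcome distributions from fitted parameter rows: discrete
# response x rating probabilities, defective / scaled RT densities, and
# density-to-quantile conversion.

.fit_table_rows <- function(fits) {
  if (is.null(fits$model)) stop("input needs a 'model' column", call. = FALSE)
  lapply(seq_len(nrow(as.data.frame(fits))), function(i) {
    as.list(as.data.frame(fits)[i, , drop = FALSE])
  })
}

# density of one outcome cell as a function of rt (vectorized)
.cell_density <- function(par_row, model, S, l, R, rating, K, L, precision,
                          simult_conf) {
  d <- unlist(par_row[paste0("d", seq_len(L))])
  function(rt) {
    tr <- data.frame(subject = 1, stimulus = S,
                     condition = factor(l, levels = seq_len(L)),
                     response = R, rt = rt, rating = rating,
                     correct = as.integer(S == R))
    attr(tr, "n_ratings") <- K
    .trial_density(par_row, model, tr, precision, simult_conf)
  }
}

.row_L <- function(p) length(grep("^d[0-9]+$", names(p)))

#' Predict the discrete choice and confidence distribution
#'
#' For every stimulus x condition x response x rating cell, integrates the
#' model's joint density over response time by adaptive quadrature
#' (\code{\link[stats]{integrate}}) and reports the outcome probability
#' together with integration diagnostics.
#'
#' @param fits one-row parameter list or a fit table (multiple rows need
#'   \code{subject} and \code{model} columns).
#' @param precision density precision (default 6).
#' @param simult_conf simultaneous choice/confidence report.
#' @return data frame with columns \code{subject}, \code{model},
#'   \code{stimulus}, \code{condition}, \code{response}, \code{rating},
#'   \code{p}, \code{info}, \code{err}.  Probabilities sum to 1 within
#'   each (subject, model, stimulus, condition).
#' @export
predict_conf <- function(fits, precision = 6, simult_conf = FALSE) {
  rows <- .fit_table_rows(fits)
  out <- list()
  for (p in rows) {
    model <- as.character(p$model)
    L <- .row_L(p)
    K <- .row_K(p)
    pc <- .complete_params(p, model)
    tmin <- pc$t0 + if (simult_conf && !is.null(pc$tau)) pc$tau else 0
    for (S in c(-1, 1)) for (l in seq_len(L)) {
      for (R in c(-1, 1)) for (k in seq_len(K)) {
        f <- .cell_density(p, model, S, l, R, k, K, L, precision,
                           simult_conf)
        ii <- tryCatch(integrate(f, lower = max(tmin, 0), upper = Inf,
                                 rel.tol = 1e-6, abs.tol = 1e-8,
                                 stop.on.error = FALSE),
                       error = function(e) list(value = NA_real_,
                                                message = conditionMessage(e),
                                                abs.error = NA_real_))
        out[[length(out) + 1]] <- data.frame(
          subject = if (!is.null(p$subject)) p$subject else 1,
          model = model, stimulus = S, condition = l, response = R,
          rating = k, p = ii$value, info = ii$message,
          err = ii$abs.error)
      }
    }
  }
  do.call(rbind, out)
}

#' Predict response-time densities
#'
#' Evaluates the defective joint density on an equidistant RT grid for
#' every outcome cell; with \code{scaled = TRUE} also the conditional
#' density (defective density divided by the cell probability, taken from
#' \code{dist_conf} if supplied, else recomputed).
#'
#' @inheritParams predict_conf
#' @param rt_grid numeric vector \code{c(min, max, step)} describing the
#'   equidistant grid (default 0 to 9 s in steps of 0.01 s).
#' @param scaled also return \code{densscaled}.
#' @param dist_conf optional output of \code{\link{predict_conf}} for the
#'   same fits (same subjects, models and coding).
#' @return data frame with columns as \code{\link{predict_conf}} plus
#'   \code{rt} and \code{dens} (and \code{densscaled}).
#' @export
predict_rt <- function(fits, rt_grid = c(0, 9, 0.01), scaled = FALSE,
                       dist_conf = NULL, precision = 6,
                       simult_conf = FALSE) {
  stopifnot(length(rt_grid) == 3, rt_grid[3] > 0)
  grid <- seq(rt_grid[1], rt_grid[2], by = rt_grid[3])
  rows <- .fit_table_rows(fits)
  if (scaled && is.null(dist_conf)) {
    dist_conf <- predict_conf(fits, precision = precision,
                              simult_conf = simult_conf)
  }
  out <- list()
  for (p in rows) {
    model <- as.character(p$model)
    L <- .row_L(p)
    K <- .row_K(p)
    subj <- if (!is.null(p$subject)) p$subject else 1
    for (S in c(-1, 1)) for (l in seq_len(L)) {
      for (R in c(-1, 1)) for (k in seq_len(K)) {
        f <- .cell_density(p, model, S, l, R, k, K, L, precision,
                           simult_conf)
        dens <- f(grid)
        cell <- data.frame(subject = subj, model = model, stimulus = S,
                           condition = l, response = R, rating = k,
                           rt = grid, dens = dens)
        if (scaled) {
          sel <- dist_conf$subject == subj & dist_conf$model == model &
            dist_conf$stimulus == S & dist_conf$condition == l &
            dist_conf$response == R & dist_conf$rating == k
          if (sum(sel) != 1) {
            stop("dist_conf does not match the fits (missing cell)",
                 call. = FALSE)
          }
          pcell <- dist_conf$p[sel]
          cell$densscaled <- if (is.finite(pcell) && pcell > 0)
            dens / pcell else 0
        }
        out[[length(out) + 1]] <- cell
      }
    }
  }
  do.call(rbind, out)
}

#' Quantiles from gridded probability density values
#'
#' Per group, normalizes the density over its RT grid and returns the
#' smallest grid point at which the cumulative sum reaches each
#' probability (left-continuous inverse of the discretized CDF).
#'
#' @param density_table data frame with columns \code{rt}, \code{dens}
#'   and any grouping columns.
#' @param probs probabilities in (0, 1).
#' @param group_cols character vector of grouping column names.
#' @return data frame of group values, \code{prob} and \code{q}; groups
#'   whose density is all zero are flagged with \code{NA} quantiles.
#' @export
pdf_to_quantiles <- function(density_table, probs = c(0.1, 0.5, 0.9),
                             group_cols = NULL) {
  stopifnot(all(probs > 0 & probs < 1))
  if (any(density_table$dens < 0, na.rm = TRUE))
    stop("densities must be nonnegative", call. = FALSE)
  key <- if (is.null(group_cols)) rep("all", nrow(density_table))
    else do.call(paste, c(density_table[group_cols], sep = "\r"))
  out <- list()
  for (g in split(seq_len(nrow(density_table)), key)) {
    dd <- density_table[g, ]
    ord <- order(dd$rt)
    dd <- dd[ord, ]
    tot <- sum(dd$dens)
    qs <- if (tot <= 0) rep(NA_real_, length(probs)) else {
      cdf <- cumsum(dd$dens) / tot
      vapply(probs, function(pr) dd$rt[which(cdf >= pr)[1]], numeric(1))
    }
    base <- if (is.null(group_cols)) data.frame(row.names = seq_along(probs))
      else dd[rep(1, length(probs)), group_cols, drop = FALSE]
    base$prob <- probs
    base$q <- qs
    out[[length(out) + 1]] <- base
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
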