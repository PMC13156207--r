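# Trial-level data model: ingestion with column aliasing, +/-1 recoding of
# stimulus and response, rating-scale bookkeeping, per-subject splitting and
# an explicit RT outlier filter.

.subject_aliases <- c("participant", "subject", "sbj")

.find_col <- function(nms, canonical, aliases = canonical) {
  hit <- which(tolower(nms) %in% tolower(aliases))
  if (length(hit) == 0) return(NA_integer_)
  hit[1]
}

.recode_pm1 <- function(x, what) {
  ux <- sort(unique(x[!is.na(x)]))
  if (length(ux) > 2) {
    stop(what, " column has ", length(ux), " distinct values; two expected",
         call. = FALSE)
  }
  if (is.numeric(x) && all(ux %in% c(-1, 1))) return(as.integer(x))
  if (length(ux) == 1) {
    # single observed level: keep sign if already signed, else map to +1
    if (is.numeric(x) && ux %in% c(-1, 1)) return(as.integer(x))
    return(rep.int(1L, length(x)))
  }
  # two levels mapped to (-1, +1) by sorted order
  ifelse(x == ux[1], -1L, 1L)
}

#' Read and encode a trial table
#'
#' Ingests a tidy trial table (one row per trial) from a data frame or a
#' delimited text file (comma, semicolon, tab or whitespace separated;
#' auto-detected).  Expected columns (default names in parentheses):
#' stimulus identity (\code{stimulus}), binary response (\code{response}),
#' response time in seconds (\code{rt}), confidence rating (\code{rating}),
#' and optionally accuracy (\code{correct}), difficulty condition
#' (\code{condition}) and a subject identifier (\code{participant},
#' \code{subject} or \code{sbj}).  One of \code{stimulus}/\code{response}
#' may be absent and is reconstructed from \code{correct}.  Alternative
#' column names are supplied as e.g. \code{rating = "confidence"}.
#'
#' Stimulus and response are recoded to \{-1, +1\} by sorted value order
#' (signed values are kept).  Ratings given as a factor are encoded by
#' level order; numeric ratings must be integers in 1..K.  RTs are expected
#' in seconds; no unit conversion is attempted.
#'
#' @param data data frame or path to a delimited text file.
#' @param n_ratings number of rating-scale points K; defaults to the
#'   maximum observed rating level.  Recommended, because a subject may not
#'   use the full scale.
#' @param ... column aliases, e.g. \code{rating = "confidence"}.
#' @return a \code{conf_trials} data frame with columns \code{subject},
#'   \code{stimulus}, \code{condition} (factor), \code{response},
#'   \code{rt}, \code{rating}, \code{correct}, and attributes
#'   \code{n_ratings} and \code{rating_info} (categories used per response
#'   sign).
#' @export
ingest_trials <- function(data, n_ratings = NULL, ...) {
  aliases <- list(...)
  if (is.character(data) && length(data) == 1) {
    header <- readLines(data, n = 1)
    sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";"
      else if (grepl(",", header)) "," else ""
    data <- read.table(data, header = TRUE, sep = sep,
                       stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(data))
  nms <- names(data)
  pick <- function(canonical, extra = character()) {
    if (!is.null(aliases[[canonical]])) {
      i <- which(nms == aliases[[canonical]])
      if (length(i) == 0) {
        stop("aliased column '", aliases[[canonical]], "' (for ", canonical,
             ") not found", call. = FALSE)
      }
      return(i[1])
    }
    .find_col(nms, canonical, c(canonical, extra))
  }
  i_stim <- pick("stimulus")
  i_resp <- pick("response")
  i_corr <- pick("correct")
  i_rt <- pick("rt")
  i_rating <- pick("rating")
  i_cond <- pick("condition")
  i_subj <- pick("subject", .subject_aliases)

  if (is.na(i_rt)) stop("mandatory column 'rt' not found", call. = FALSE)
  if (is.na(i_rating)) stop("mandatory column 'rating' not found", call. = FALSE)
  if (is.na(i_stim) && is.na(i_corr))
    stop("need a 'stimulus' or 'correct' column", call. = FALSE)
  if (is.na(i_resp) && is.na(i_corr))
    stop("need a 'response' or 'correct' column", call. = FALSE)

  rt <- as.numeric(data[[i_rt]])
  bad <- which(!is.finite(rt) | rt <= 0)
  if (length(bad) > 0) {
    stop("non-positive or non-finite rt in rows: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  }

  stimulus <- if (!is.na(i_stim)) .recode_pm1(data[[i_stim]], "stimulus") else NULL
  response <- if (!is.na(i_resp)) .recode_pm1(data[[i_resp]], "response") else NULL
  correct <- if (!is.na(i_corr)) {
    co <- as.integer(data[[i_corr]])
    if (!all(co %in% c(0L, 1L))) stop("'correct' must be 0/1", call. = FALSE)
    co
  } else NULL

  if (is.null(response)) response <- stimulus * (2L * correct - 1L)
  if (is.null(stimulus)) stimulus <- response * (2L * correct - 1L)
  if (is.null(correct)) {
    correct <- as.integer(stimulus == response)
  } else if (!is.na(i_stim) && !is.na(i_resp)) {
    if (any(correct != as.integer(stimulus == response))) {
      stop("'correct' column conflicts with stimulus/response coding; ",
           "refusing to silently prefer either", call. = FALSE)
    }
  }

  rating_raw <- data[[i_rating]]
  if (is.factor(rating_raw) || is.character(rating_raw)) {
    f <- if (is.factor(rating_raw)) rating_raw else factor(rating_raw)
    rating <- as.integer(f)
    K <- if (is.null(n_ratings)) nlevels(f) else n_ratings
  } else {
    rating <- as.integer(rating_raw)
    if (any(rating_raw != rating)) stop("ratings must be integers", call. = FALSE)
    K <- if (is.null(n_ratings)) max(rating) else n_ratings
  }
  if (any(rating < 1 | rating > K)) {
    stop("rating values outside 1..", K, call. = FALSE)
  }
  if (K < 2) stop("need at least 2 rating categories", call. = FALSE)

  condition <- if (!is.na(i_cond)) factor(data[[i_cond]]) else factor(rep(1, nrow(data)))
  subject <- if (!is.na(i_subj)) data[[i_subj]] else rep(1L, nrow(data))

  out <- data.frame(subject = subject, stimulus = stimulus,
                    condition = condition, response = response,
                    rt = rt, rating = rating, correct = correct)
  attr(out, "n_ratings") <- K
  attr(out, "rating_info") <- list(
    K = K,
    used = list(`-1` = sort(unique(rating[response == -1L])),
                `1` = sort(unique(rating[response == 1L]))))
  class(out) <- c("conf_trials", "data.frame")
  out
}

#' Split a trial table by subject
#'
#' @param trials data frame with a subject column (aliases
#'   \code{participant}, \code{subject}, \code{sbj} accepted).
#' @return named list of per-subject tables; a single-group list with a
#'   warning when no subject column is present.
#' @export
split_by_subject <- function(trials) {
  i <- .find_col(names(trials), "subject", c("subject", .subject_aliases))
  if (is.na(i)) {
    warning("no subject column found; treating data as a single group")
    return(if (nrow(trials) == 0) list() else list(`1` = trials))
  }
  if (nrow(trials) == 0) return(list())
  sp <- split(seq_len(nrow(trials)), trials[[i]])
  lapply(sp, function(idx) {
    out <- trials[idx, , drop = FALSE]
    attributes(out)[c("n_ratings", "rating_info")] <-
      attributes(trials)[c("n_ratings", "rating_info")]
    out
  })
}

#' Filter response-time outliers
#'
#' Removes, per subject, trials with \code{rt < lower} or
#' \code{rt > mean(rt) + k_sd * sd(rt)}.  No filtering is applied
#' automatically anywhere in the package; exclusion rules are the user's
#' choice.
#'
#' @param trials trial table (see \code{\link{ingest_trials}}).
#' @param lower absolute lower cutoff in seconds.
#' @param k_sd multiplier of the per-subject RT standard deviation for the
#'   upper cutoff.
#' @return the filtered table; the fraction removed is reported as a message.
#' @export
filter_rt_outliers <- function(trials, lower = 0.3, k_sd = 2) {
  keep <- rep(TRUE, nrow(trials))
  for (idx in split(seq_len(nrow(trials)), trials$subject)) {
    rt <- trials$rt[idx]
    up <- mean(rt) + k_sd * sd(rt)
    keep[idx] <- rt >= lower & rt <= up
  }
  message(sprintf("removed %.1f%% of trials", 100 * mean(!keep)))
  out <- trials[keep, , drop = FALSE]
  attributes(out)[c("n_ratings", "rating_info")] <-
    attributes(trials)[c("n_ratings", "rating_info")]
  out
}

# K for a trial table: attribute if present, else max observed rating
.get_K <- function(trials, n_ratings = NULL) {
  if (!is.null(n_ratings)) return(n_ratings)
  K <- attr(trials, "n_ratings")
  if (is.null(K)) K <- max(trials$rating)
  K
}
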