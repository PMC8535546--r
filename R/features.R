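#' Canonical clustering feature names
#'
#' The 18 behavioural features computed from a user's first 90 days:
#' three monthly means of daily workout seconds, three monthly missed-day
#' counts, and twelve weekly means.
#'
#' @return Character vector of length 18.
#' @export
feature_names <- function() {
  c("mean_first_month", "mean_second_month", "mean_third_month",
    "missed_first_month", "missed_second_month", "missed_third_month",
    paste0("mean_week_", 1:12))
}

#' Extract the 18 clustering features from a daily series
#'
#' Months are fixed 30-day blocks of the first 90 days (month m = days
#' `30(m-1)+1 ... 30m`); weeks are fixed 7-day blocks covering days 1-84.
#' A "missed" day is a day with zero accumulated workout seconds: the app
#' prescribes no schedule, so inactivity is the observable notion of a
#' skipped session.
#'
#' @param series a `daily_series` (length >= 90) or a plain numeric vector.
#' @return Named numeric vector of length 18 (see [feature_names()]).
#' @export
#' @examples
#' s <- daily_series("u1", rep(c(300, 0), 60))
#' extract_features(s)[c("mean_first_month", "missed_first_month")]
extract_features <- function(series) {
  v <- if (inherits(series, "daily_series")) series$values else as.numeric(series)
  if (length(v) < 90L)
    stop("need at least 90 days to extract features, got ", length(v),
         call. = FALSE)
  months <- lapply(1:3, function(m) v[(30L * (m - 1L) + 1L):(30L * m)])
  weeks  <- lapply(1:12, function(w) v[(7L * (w - 1L) + 1L):(7L * w)])
  out <- c(vapply(months, mean, numeric(1)),
           vapply(months, function(b) sum(b == 0), numeric(1)),
           vapply(weeks, mean, numeric(1)))
  names(out) <- feature_names()
  out
}

#' Feature presets
#'
#' Named feature subsets used when clustering:
#' * `month_means` - the three monthly means;
#' * `missed_months` - the three monthly missed-day counts;
#' * `weeks` - the twelve weekly means;
#' * `combined` - missed-day counts + monthly means + weeks 8-11 (10 features);
#' * `all` - every feature (18).
#'
#' @param preset preset name.
#' @return Character vector of feature names, in their documented order.
#' @export
feature_preset <- function(preset = c("combined", "month_means",
                                      "missed_months", "weeks", "all")) {
  preset <- match.arg(preset)
  switch(preset,
    month_means   = feature_names()[1:3],
    missed_months = feature_names()[4:6],
    weeks         = feature_names()[7:18],
    combined      = c(feature_names()[4:6], feature_names()[1:3],
                      paste0("mean_week_", 8:11)),
    all           = feature_names()
  )
}

#' Select (and optionally standardize) a feature preset
#'
#' @param fv a feature vector from [extract_features()], or a matrix with
#'   the 18 canonical columns (rows = users).
#' @param preset preset name (see [feature_preset()]).
#' @param standardize z-score the selected features? Defaults to `FALSE`
#'   (the distance-based threshold reasoning for BIRCH is done in raw
#'   seconds). Constant features standardize to 0.
#' @param center,scale cohort-level means/sds to standardize against (as
#'   stored at fit time); computed from `fv` itself when omitted and `fv`
#'   is a matrix.
#' @return Numeric vector (or matrix) of the selected features.
#' @export
select_preset <- function(fv, preset = "combined", standardize = FALSE,
                          center = NULL, scale = NULL) {
  cols <- feature_preset(preset)
  x <- if (is.matrix(fv)) fv[, cols, drop = FALSE] else fv[cols]
  if (standardize) {
    if (is.null(center)) {
      if (!is.matrix(x))
        stop("standardizing a single vector needs cohort `center`/`scale`",
             call. = FALSE)
      center <- colMeans(x)
      scale <- apply(x, 2, sd)
    } else {
      center <- center[cols]
      scale <- scale[cols]
    }
    scale[!is.finite(scale) | scale == 0] <- 1  # constant feature -> 0
    x <- if (is.matrix(x)) sweep(sweep(x, 2, center), 2, scale, "/")
         else (x - center) / scale
  }
  x
}

#' Feature matrix for a cohort
#'
#' @param cohort list of `daily_series`.
#' @return Matrix (users x 18) with canonical column names and user ids as
#'   row names.
#' @export
cohort_features <- function(cohort) {
  m <- t(vapply(cohort, function(s) extract_features(s), numeric(18)))
  rownames(m) <- vapply(cohort, function(s) as.character(s$user_id),
                        character(1))
  m
}
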