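#' Train the cluster-conditioned ensemble framework
#'
#' Fits the full pipeline on a cohort of 120-day series: clustering on the
#' selected feature preset of the first 90 days, then a per-user
#' grid-searched forecaster trained on the 90-day training window only
#' (month 4 is never shown to any model), grouped into per-cluster
#' ensembles.
#'
#' @param cohort list of `daily_series` (length 120 each).
#' @param clustering list describing the clustering stage:
#'   `method` one of `"kmeans"`, `"birch"`, `"ap"`, `"none"` (the
#'   single-ensemble baseline), plus method parameters (`k`,
#'   `threshold`/`branching`/`n_global_clusters`,
#'   `damping`/`preference`).
#' @param regressor list with `kind` (`"svr"` or `"lstm"`) and optional
#'   `grid` (list of spec objects; defaults to the full grid for the kind).
#' @param preset feature preset name (see [feature_preset()]).
#' @param standardize z-score features before clustering? Cohort statistics
#'   are stored and reapplied to new users.
#' @param tau adherence threshold in predicted seconds per month (see
#'   [predicted_label()]), or `"auto"` (the default) to calibrate it at fit
#'   time. Recursive regression forecasts carry a positive noise floor (of
#'   the order of the SVR tube width per day), so a threshold near zero
#'   labels everyone adherent; `"auto"` computes every training user's
#'   in-sample ensemble forecast total and picks the threshold maximising
#'   balanced accuracy against the training adherence labels. Month-4 data
#'   is still never shown to any regressor — labels enter only this scalar
#'   classification cut-off.
#' @param seed seed for clustering restarts and regressor training.
#' @return A `framework_model`.
#' @export
train_framework <- function(cohort,
                            clustering = list(method = "kmeans", k = 4L),
                            regressor = list(kind = "svr"),
                            preset = "combined", standardize = FALSE,
                            tau = "auto", seed = 1L) {
  if (length(cohort) == 0L) stop("empty cohort", call. = FALSE)
  feats <- cohort_features(cohort)
  center <- colMeans(feats)
  scl <- apply(feats, 2, sd)
  X <- select_preset(feats, preset, standardize, center, scl)
  cm <- fit_clustering(X, clustering, seed)
  labels <- if (!is.null(cm$labels) && length(cm$labels) == nrow(X))
    as.integer(cm$labels)
  else
    vapply(seq_len(nrow(X)), function(i) assign_cluster(cm, X[i, ]),
           integer(1))
  kind <- match.arg(regressor$kind, c("svr", "lstm"))
  grid <- regressor$grid
  members <- list()
  kept <- logical(length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    train <- split_windows(s)$train
    reg <- tryCatch(
      grid_search_user(train, kind, grid, seed = seed + i),
      error = function(e) {
        warning("user ", s$user_id, " excluded: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(reg)) next
    kept[i] <- TRUE
    members[[length(members) + 1L]] <-
      list(user_id = s$user_id, cluster = labels[i], regressor = reg)
  }
  if (!length(members)) stop("no user could be fitted", call. = FALSE)
  model <- structure(list(
    clustering = cm, method = clustering$method, labels = labels,
    preset = preset, standardize = standardize,
    center = center, scale = scl,
    members = members, regressor_kind = kind, tau = NA_real_,
    user_ids = vapply(members, `[[`, character(1), "user_id")
  ), class = "framework_model")
  model$tau <- if (identical(tau, "auto")) calibrate_tau(model, cohort)
               else as.numeric(tau)
  model
}

# Threshold calibration: in-sample ensemble forecast totals vs training
# labels, scanned over midpoints of consecutive totals; best balanced
# accuracy wins, ties to the smallest threshold.
calibrate_tau <- function(model, cohort, fallback = 60) {
  ok <- vapply(cohort, function(s) length(s$values) == 120L, logical(1))
  if (!all(ok)) return(fallback)
  truth <- vapply(cohort, true_label, character(1))
  if (length(unique(truth)) < 2L) return(fallback)
  totals <- vapply(cohort, function(s)
    sum(predict_month4(model, split_windows(s)$train)), numeric(1))
  cand <- sort(unique(totals))
  cand <- c(cand[1] / 2, (cand[-1] + cand[-length(cand)]) / 2,
            cand[length(cand)] + 1)
  pos <- truth == "adherent"
  bal <- vapply(cand, function(th) {
    pred <- totals >= th
    (mean(pred[pos]) + mean(!pred[!pos])) / 2
  }, numeric(1))
  cand[which.max(bal)]
}

fit_clustering <- function(X, config, seed) {
  method <- match.arg(config$method, c("kmeans", "birch", "ap", "none"))
  switch(method,
    kmeans = kmeans_fit(X, k = config$k %||% 4L,
                        max_iter = config$max_iter %||% 100L,
                        n_restarts = config$n_restarts %||% 10L,
                        seed = seed),
    birch = birch_fit(X, threshold = config$threshold %||% 0.1,
                      branching = config$branching %||% 50L,
                      n_global_clusters = config$n_global_clusters %||%
                        config$k %||% 4L),
    ap = ap_fit(X, damping = config$damping %||% 0.7,
                preference = config$preference %||% "median",
                max_iter = config$max_iter %||% 200L,
                convergence_iter = config$convergence_iter %||% 15L,
                seed = seed),
    none = structure(list(), class = "no_clustering")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
assign_cluster.no_clustering <- function(model, fv, ...) 1L

#' @export
n_clusters.no_clustering <- function(model) 1L

#' @export
print.framework_model <- function(x, ...) {
  tab <- table(vapply(x$members, `[[`, integer(1), "cluster"))
  cat("Adherence framework:", x$method, "clustering +", x$regressor_kind,
      "forecasters\n ", length(x$members), "ensemble members in",
      length(tab), "clusters (sizes:", paste(tab, collapse = ", "), ")\n")
  invisible(x)
}

#' Predict a new user's fourth month
#'
#' Extracts the new user's features, assigns a cluster, lets every member
#' of that cluster's ensemble forecast 30 days from the user's history
#' (each member applies its own scaling transform to the new history), and
#' averages the forecasts elementwise. An empty cluster — including the
#' affinity-propagation non-convergence sentinel `-1` — falls back to the
#' global ensemble of all members, i.e. the single-ensemble baseline.
#'
#' @param model a fitted `framework_model`.
#' @param first_90_days the user's first 90 daily values (a 90-vector, or a
#'   `daily_series` whose training window is used).
#' @param horizon forecast length (default 30 days).
#' @param exclude_user optional member user id excluded from the ensemble
#'   (leave-one-user-out evaluation).
#' @return Numeric vector of `horizon` mean forecasts (seconds/day).
#' @export
predict_month4 <- function(model, first_90_days, horizon = 30L,
                           exclude_user = NULL) {
  if (!inherits(model, "framework_model"))
    stop("model is not a fitted framework_model", call. = FALSE)
  v <- if (inherits(first_90_days, "daily_series")) first_90_days$values
       else as.numeric(first_90_days)
  if (length(v) < 90L) stop("need 90 days of history", call. = FALSE)
  v <- v[1:90]
  fv <- select_preset(extract_features(v), model$preset, model$standardize,
                      model$center, model$scale)
  cl <- assign_cluster(model$clustering, fv)
  ens <- ensemble_members(model, cl, exclude_user)
  if (!length(ens)) ens <- ensemble_members(model, NULL, exclude_user)
  preds <- vapply(ens, function(m)
    forecast_recursive(m$regressor, v, horizon), numeric(horizon))
  rowMeans(matrix(preds, nrow = horizon))
}

ensemble_members <- function(model, cluster = NULL, exclude_user = NULL) {
  keep <- vapply(model$members, function(m) {
    (is.null(cluster) || m$cluster == cluster) &&
      (is.null(exclude_user) || m$user_id != exclude_user)
  }, logical(1))
  model$members[keep]
}

#' Leave-one-user-out evaluation
#'
#' Trains the framework on the full cohort, then predicts every user's
#' fourth month from their first 90 days using their cluster's ensemble
#' *excluding their own member*, and scores the binarised predictions
#' against the true adherence labels. (The held-out user still contributes
#' to the fitted clustering; only their forecaster is excluded.)
#'
#' @inheritParams train_framework
#' @param horizon forecast length (default 30).
#' @return List with `results` (data.frame: `user_id`, `cluster`,
#'   `predicted_total_s`, `true_label`, `predicted_label`), `predictions`
#'   (users x horizon matrix), `confusion`, `metrics` and the fitted
#'   `model`.
#' @export
loo_evaluate <- function(cohort,
                         clustering = list(method = "kmeans", k = 4L),
                         regressor = list(kind = "svr"),
                         preset = "combined", standardize = FALSE,
                         tau = "auto", horizon = 30L, seed = 1L) {
  if (length(cohort) < 2L) stop("need a cohort of at least 2", call. = FALSE)
  model <- train_framework(cohort, clustering, regressor, preset,
                           standardize, tau, seed)
  n <- length(cohort)
  preds <- matrix(0, n, horizon)
  res <- data.frame(
    user_id = vapply(cohort, function(s) as.character(s$user_id),
                     character(1)),
    cluster = NA_integer_, predicted_total_s = NA_real_,
    true_label = NA_character_, predicted_label = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    s <- cohort[[i]]
    train <- split_windows(s)$train
    p <- predict_month4(model, train, horizon, exclude_user = s$user_id)
    preds[i, ] <- p
    res$cluster[i] <- model$labels[i]
    res$predicted_total_s[i] <- sum(p)
    res$true_label[i] <- true_label(s)
    res$predicted_label[i] <- predicted_label(p, model$tau)
  }
  cm <- confusion(res$true_label, res$predicted_label)
  list(results = res, predictions = preds, confusion = cm,
       metrics = metrics(cm), model = model)
}

#' Save / load a fitted framework
#'
#' Binary single-file bundle (RDS) of the full `framework_model`.
#'
#' @param model a `framework_model`.
#' @param path file path.
#' @return `load_framework` returns the model, invisibly for `save`.
#' @export
save_framework <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_framework
#' @export
load_framework <- function(path) readRDS(path)
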