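#' Default hyperparameter grids
#'
#' `default_svr_grid()` crosses the three kernels (polynomial, radial,
#' sigmoid) with `C` in {1, 10, 50, 100, 200, 500} — a discrete sweep of
#' the (0, 500] penalty range — keeping epsilon at 10 s and the
#' data-scaled gamma. `default_lstm_grid()` crosses dropout {0.2, 0.4,
#' 0.6} x batch size {1, 2, 4} x units {50, 75, 100, 125, 150}
#' (45 combinations). Grid order is the documented tie-break order:
#' combinations are trained in list order and ties in training MAE go to
#' the first.
#'
#' @return List of spec objects.
#' @export
default_svr_grid <- function() {
  grid <- list()
  for (kern in c("polynomial", "radial", "sigmoid"))
    for (C in c(1, 10, 50, 100, 200, 500))
      grid[[length(grid) + 1L]] <- svr_spec(kernel = kern, C = C)
  grid
}

#' @rdname default_svr_grid
#' @export
default_lstm_grid <- function() {
  grid <- list()
  for (dropout in c(0.2, 0.4, 0.6))
    for (batch in c(1L, 2L, 4L))
      for (units in c(50L, 75L, 100L, 125L, 150L))
        grid[[length(grid) + 1L]] <-
          lstm_spec(units = units, dropout = dropout, batch_size = batch)
  grid
}

#' A deliberately small LSTM grid for desk-scale runs
#'
#' One combination with few epochs; the full 45-point grid at 50 epochs is
#' the study-scale configuration.
#'
#' @param units,epochs reduced network width and training length.
#' @return List with one [lstm_spec()].
#' @export
reduced_lstm_grid <- function(units = 16L, epochs = 5L) {
  list(lstm_spec(units = units, dropout = 0.2, batch_size = 4L,
                 epochs = epochs))
}

#' Grid-search a user's forecaster
#'
#' Trains every spec in the grid on the user's training window and returns
#' the model with the lowest training MAE (ties: first in grid order).
#'
#' @param series the user's 90-day training window.
#' @param kind `"svr"` or `"lstm"` (used only to pick the default grid).
#' @param grid list of [svr_spec()] / [lstm_spec()] objects.
#' @param seed seed passed to each fit.
#' @return The winning `trained_regressor`.
#' @export
grid_search_user <- function(series, kind = c("svr", "lstm"), grid = NULL,
                             seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(grid))
    grid <- if (kind == "svr") default_svr_grid() else default_lstm_grid()
  if (length(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  best <- NULL
  for (spec in grid) {
    fitter <- if (inherits(spec, "svr_spec")) fit_svr else fit_lstm
    fit <- fitter(series, spec, seed = seed)
    if (is.null(best) || fit$train_mae < best$train_mae) best <- fit
  }
  best
}

#' Recursive multi-step forecast
#'
#' Rolls a one-step forecaster forward: each predicted day is appended to
#' the window and fed back as input for the next step. The new history is
#' scaled with the *model's own* min-max transform (pre-trained models are
#' reused verbatim on new users); outputs are inverse-scaled to seconds and
#' clipped at zero. On the scaled axis each prediction is clamped to the
#' `[0, 1]` training range before being fed back: the recursion otherwise
#' leaves the domain the one-step model was fitted on, and unbounded
#' kernels (polynomial, sigmoid) can diverge within a few steps.
#'
#' @param model a `trained_regressor`.
#' @param history at least `lookback` recent daily values, in seconds.
#' @param horizon days to forecast (default 30: the held-out fourth month).
#' @return Numeric vector of `horizon` non-negative forecasts (seconds).
#' @export
forecast_recursive <- function(model, history, horizon = 30L) {
  v <- if (inherits(history, "daily_series")) history$values
       else as.numeric(history)
  lb <- model$lookback
  if (length(v) < lb)
    stop("history shorter than lookback (", lb, ")", call. = FALSE)
  window <- apply_scale(model$transform, tail(v, lb))
  out <- numeric(horizon)
  for (s in seq_len(horizon)) {
    p <- predict_one_step(model, window)[1L]
    p <- min(max(p, 0), 1)
    out[s] <- max(0, inverse_scale(model$transform, p))
    window <- c(window[-1L], p)
  }
  out
}
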