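# Epsilon-tube support vector regression over sliding windows. The quadratic
# programme itself is solved by libsvm (via e1071); this file owns the
# time-series framing: per-user min-max scaling, the seconds-denominated
# tube width, the data-scaled kernel coefficient and the grid conventions.

#' SVR hyperparameter specification
#'
#' @param kernel `"radial"`, `"polynomial"` or `"sigmoid"` (the three
#'   kernels of the grid search).
#' @param C box-constraint penalty, in `(0, 500]`.
#' @param epsilon_s half-width of the insensitivity tube, in seconds
#'   (default 10 s). The model is trained on min-max-scaled targets, so the
#'   tube is converted to the scaled axis by the user's range; a tube
#'   specified directly on a `[0, 1]` axis would swallow the whole signal.
#' @param gamma kernel coefficient; `"scale"` (default) uses
#'   `1 / (d * var(X))` on the scaled inputs.
#' @param degree polynomial degree (polynomial kernel only).
#' @param coef0 additive kernel constant `r` (polynomial/sigmoid).
#' @param lookback sliding-window length.
#' @return An `svr_spec` list.
#' @export
svr_spec <- function(kernel = "radial", C = 1, epsilon_s = 10,
                     gamma = "scale", degree = 3, coef0 = 0, lookback = 7L) {
  kernel <- match.arg(kernel, c("radial", "polynomial", "sigmoid"))
  if (C <= 0) stop("C must be positive", call. = FALSE)
  structure(list(kernel = kernel, C = C, epsilon_s = epsilon_s,
                 gamma = gamma, degree = degree, coef0 = coef0,
                 lookback = as.integer(lookback)),
            class = "svr_spec")
}

#' Fit an epsilon-tube SVR forecaster on one user's series
#'
#' The series is min-max scaled, converted to `lookback`-day sliding
#' windows, and an eps-regression SVM is fitted. The reported MAE is the
#' one-step training error in original units (seconds).
#'
#' @param series the user's training window (numeric vector or
#'   `daily_series`).
#' @param spec an [svr_spec()].
#' @param seed unused (the solver is deterministic); kept for a uniform
#'   fitting signature.
#' @return A `trained_regressor` (kind `"svr"`).
#' @importFrom e1071 svm
#' @export
fit_svr <- function(series, spec = svr_spec(), seed = 1L) {
  v <- if (inherits(series, "daily_series")) series$values else as.numeric(series)
  sc <- scale_series(v)
  sup <- to_supervised(sc$scaled, spec$lookback)
  eps <- if (sc$transform$range > 0) spec$epsilon_s / sc$transform$range
         else spec$epsilon_s
  gamma <- if (identical(spec$gamma, "scale")) {
    vx <- var(as.vector(sup$inputs))
    if (is.finite(vx) && vx > 0) 1 / (ncol(sup$inputs) * vx)
    else 1 / ncol(sup$inputs)
  } else spec$gamma
  # Constant targets (e.g. an all-zero or single-burst series) leave every
  # residual inside the tube and the dual problem without support vectors;
  # the flat function through the constant is the tube-optimal fit.
  fit <- if (var(sup$targets) == 0) {
    list(constant = sup$targets[1L])
  } else {
    tryCatch(
      e1071::svm(x = sup$inputs, y = sup$targets, type = "eps-regression",
                 kernel = spec$kernel, cost = spec$C, epsilon = eps,
                 gamma = gamma, degree = spec$degree, coef0 = spec$coef0,
                 scale = FALSE),
      error = function(e) {
        if (grepl("empty", conditionMessage(e), ignore.case = TRUE))
          list(constant = mean(range(sup$targets)))
        else stop(e)
      })
  }
  pred <- if (!is.null(fit$constant)) rep(fit$constant, nrow(sup$inputs))
          else as.numeric(predict(fit, sup$inputs))
  orig <- to_supervised(v, spec$lookback)
  mae <- mean(abs(inverse_scale(sc$transform, pred) - orig$targets))
  trained_regressor(kind = "svr", fit = fit, spec = spec,
                    transform = sc$transform, train_mae = mae,
                    hyper = list(kernel = spec$kernel, C = spec$C,
                                 gamma = gamma, epsilon = eps))
}

#' Trained per-user forecaster
#'
#' Container shared by the SVR and LSTM fitters: the fitted model, the
#' hyperparameters that won the grid search, the one-step training MAE in
#' seconds, and the user's min-max transform (reapplied to any new history
#' the model forecasts from).
#'
#' @param kind `"svr"`, `"lstm"` or a custom kind (stub models in tests).
#' @param fit fitted model object.
#' @param spec the hyperparameter spec used.
#' @param transform min-max transform from [scale_series()].
#' @param train_mae training MAE, seconds.
#' @param hyper named list of resolved hyperparameters.
#' @return A `trained_regressor`.
#' @export
trained_regressor <- function(kind, fit, spec, transform, train_mae,
                              hyper = list()) {
  structure(list(kind = kind, fit = fit, spec = spec, transform = transform,
                 train_mae = train_mae, hyper = hyper,
                 lookback = spec$lookback),
            class = c(paste0(kind, "_regressor"), "trained_regressor"))
}

#' @export
print.trained_regressor <- function(x, ...) {
  cat("Trained", x$kind, "forecaster - training MAE",
      round(x$train_mae, 2), "s\n")
  invisible(x)
}

#' One-step-ahead prediction on the scaled axis
#'
#' @param model a `trained_regressor`.
#' @param window matrix of scaled `lookback`-length input windows (rows).
#' @param ... unused.
#' @return Numeric vector of scaled one-step predictions.
#' @export
predict_one_step <- function(model, window, ...) UseMethod("predict_one_step")

#' @export
predict_one_step.svr_regressor <- function(model, window, ...) {
  w <- matrix(window, ncol = model$lookback)
  if (!is.null(model$fit$constant)) return(rep(model$fit$constant, nrow(w)))
  as.numeric(predict(model$fit, w))
}
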