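# A compact univariate LSTM forecaster written directly against the cell
# equations: logistic input/forget/output gates with peephole connections,
# tanh cell candidate and hidden nonlinearity,
#   i_t = sigma(W_xi x_t + W_hi h_{t-1} + w_ci . c_{t-1} + b_i)
#   f_t = sigma(W_xf x_t + W_hf h_{t-1} + w_cf . c_{t-1} + b_f)
#   c_t = f_t . c_{t-1} + i_t . tanh(W_xc x_t + W_hc h_{t-1} + b_c)
#   o_t = sigma(W_xo x_t + W_ho h_{t-1} + w_co . c_t + b_o)
#   h_t = o_t . tanh(c_t)
# followed by three dense layers (ReLU, ReLU, linear) with one shared
# dropout rate after the first and second dense layers. Trained by
# backpropagation through time with Adam on the mean-squared error,
# stopping early when the training loss stalls. Gate pre-activations are
# packed [i | f | g | o] into one 4U block per step.

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

#' LSTM hyperparameter specification
#'
#' One recurrent layer of `units` cells feeding three dense layers of
#' widths `units/2`, `units/4` and 1 (linear output). The grid-searched
#' hyperparameters are `units` (50/75/100/125/150), `dropout`
#' (0.2/0.4/0.6, one shared rate at both dropout sites) and `batch_size`
#' (1/2/4); epochs are fixed at 50 with early stopping at patience 15 on
#' the training loss.
#'
#' @param units LSTM layer width.
#' @param dropout shared dropout rate after the first and second dense
#'   layers.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without training-loss
#'   improvement).
#' @param learning_rate Adam step size.
#' @param lookback sliding-window length in days.
#' @return An `lstm_spec` list.
#' @export
lstm_spec <- function(units = 50L, dropout = 0.2, batch_size = 1L,
                      epochs = 50L, patience = 15L, learning_rate = 1e-3,
                      lookback = 7L) {
  stopifnot(units >= 2, dropout >= 0, dropout < 1, batch_size >= 1)
  structure(list(units = as.integer(units), dropout = dropout,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 learning_rate = learning_rate,
                 lookback = as.integer(lookback)),
            class = "lstm_spec")
}

# ---- parameters ---------------------------------------------------------

lstm_init <- function(spec) {
  U <- spec$units
  d1 <- max(1L, U %/% 2L)
  d2 <- max(1L, U %/% 4L)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  b <- numeric(4L * U)
  b[(U + 1L):(2L * U)] <- 1  # forget-gate bias starts open
  list(
    Wx = glorot(4L * U, 1L)[, 1L],  # scalar input
    Wh = glorot(4L * U, U),
    b  = b,
    wci = numeric(U), wcf = numeric(U), wco = numeric(U),
    W1 = glorot(d1, U), b1 = numeric(d1),
    W2 = glorot(d2, d1), b2 = numeric(d2),
    W3 = glorot(1L, d2), b3 = numeric(1L)
  )
}

# ---- forward ------------------------------------------------------------

# One window (scaled scalar sequence). Returns prediction and, if
# keep_state, everything the backward pass needs. masks: NULL (no dropout)
# or list(m1, m2) of inverted-dropout masks.
lstm_forward <- function(par, xs, masks = NULL, keep_state = FALSE) {
  U <- length(par$wci)
  Tn <- length(xs)
  h <- numeric(U); cc <- numeric(U)
  st <- if (keep_state) vector("list", Tn)
  ii <- 1:U; fi <- (U + 1L):(2L * U)
  gi <- (2L * U + 1L):(3L * U); oi <- (3L * U + 1L):(4L * U)
  for (t in seq_len(Tn)) {
    a <- par$Wx * xs[t] + as.numeric(par$Wh %*% h) + par$b
    ig <- sigmoid(a[ii] + par$wci * cc)
    fg <- sigmoid(a[fi] + par$wcf * cc)
    gg <- tanh(a[gi])
    c_new <- fg * cc + ig * gg
    og <- sigmoid(a[oi] + par$wco * c_new)
    h_new <- og * tanh(c_new)
    if (keep_state)
      st[[t]] <- list(x = xs[t], h_prev = h, c_prev = cc, i = ig, f = fg,
                      g = gg, o = og, c = c_new, tc = tanh(c_new))
    h <- h_new; cc <- c_new
  }
  z1 <- as.numeric(par$W1 %*% h) + par$b1
  a1 <- relu(z1)
  d1 <- if (is.null(masks)) a1 else a1 * masks$m1
  z2 <- as.numeric(par$W2 %*% d1) + par$b2
  a2 <- relu(z2)
  d2 <- if (is.null(masks)) a2 else a2 * masks$m2
  y <- as.numeric(par$W3 %*% d2) + par$b3
  if (!keep_state) return(y)
  list(y = y, h = h, st = st, z1 = z1, a1 = a1, d1 = d1,
       z2 = z2, a2 = a2, d2 = d2)
}

# ---- backward -----------------------------------------------------------

# Gradient of 0.5 * (y - target)^2 for one window.
lstm_backward <- function(par, fw, target, masks = NULL) {
  U <- length(par$wci)
  g <- lapply(par, function(p) p * 0)
  dy <- fw$y - target
  g$W3 <- matrix(fw$d2 * dy, 1L)
  g$b3 <- dy
  dd2 <- as.numeric(t(par$W3) * dy)
  if (!is.null(masks)) dd2 <- dd2 * masks$m2
  dz2 <- dd2 * (fw$z2 > 0)
  g$W2 <- outer(dz2, fw$d1)
  g$b2 <- dz2
  dd1 <- as.numeric(t(par$W2) %*% dz2)
  if (!is.null(masks)) dd1 <- dd1 * masks$m1
  dz1 <- dd1 * (fw$z1 > 0)
  g$W1 <- outer(dz1, fw$h)
  g$b1 <- dz1
  dh <- as.numeric(t(par$W1) %*% dz1)
  dc <- numeric(U)
  for (t in rev(seq_along(fw$st))) {
    s <- fw$st[[t]]
    da_o <- dh * s$tc * s$o * (1 - s$o)
    dct <- dc + dh * s$o * (1 - s$tc^2) + da_o * par$wco
    da_i <- dct * s$g * s$i * (1 - s$i)
    da_f <- dct * s$c_prev * s$f * (1 - s$f)
    da_g <- dct * s$i * (1 - s$g^2)
    dA <- c(da_i, da_f, da_g, da_o)
    g$Wx <- g$Wx + dA * s$x
    g$Wh <- g$Wh + outer(dA, s$h_prev)
    g$b <- g$b + dA
    g$wci <- g$wci + da_i * s$c_prev
    g$wcf <- g$wcf + da_f * s$c_prev
    g$wco <- g$wco + da_o * s$c
    dc <- dct * s$f + da_i * par$wci + da_f * par$wcf
    dh <- as.numeric(t(par$Wh) %*% dA)
  }
  g
}

# ---- training -----------------------------------------------------------

#' Fit an LSTM forecaster on one user's series
#'
#' Min-max scales the series, converts it to sliding windows and trains the
#' network by BPTT/Adam for at most `spec$epochs` epochs, stopping early
#' when the training loss has not improved for `spec$patience` epochs. The
#' reported MAE is the one-step training error in original units.
#'
#' @param series the user's training window (numeric vector or
#'   `daily_series`).
#' @param spec an [lstm_spec()].
#' @param seed seed controlling initialisation, shuffling and dropout.
#' @return A `trained_regressor` (kind `"lstm"`).
#' @export
fit_lstm <- function(series, spec = lstm_spec(), seed = 1L) {
  v <- if (inherits(series, "daily_series")) series$values else as.numeric(series)
  sc <- scale_series(v)
  sup <- to_supervised(sc$scaled, spec$lookback)
  n <- nrow(sup$inputs)
  par <- NULL
  with_seed(seed, {
    par <- lstm_init(spec)
    m <- lapply(par, function(p) p * 0)  # Adam moments
    vv <- lapply(par, function(p) p * 0)
    step <- 0L
    best_loss <- Inf
    wait <- 0L
    d1n <- length(par$b1); d2n <- length(par$b2)
    keep <- 1 - spec$dropout
    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / spec$batch_size))) {
        gacc <- NULL
        for (j in bs) {
          masks <- if (spec$dropout > 0)
            list(m1 = (runif(d1n) < keep) / keep,
                 m2 = (runif(d2n) < keep) / keep) else NULL
          fw <- lstm_forward(par, sup$inputs[j, ], masks, keep_state = TRUE)
          ep_loss <- ep_loss + (fw$y - sup$targets[j])^2
          gj <- lstm_backward(par, fw, sup$targets[j], masks)
          gacc <- if (is.null(gacc)) gj
                  else Map(`+`, gacc, gj)
        }
        gacc <- lapply(gacc, function(g) g / length(bs))
        step <- step + 1L
        for (nm in names(par)) {
          m[[nm]] <- 0.9 * m[[nm]] + 0.1 * gacc[[nm]]
          vv[[nm]] <- 0.999 * vv[[nm]] + 0.001 * gacc[[nm]]^2
          mhat <- m[[nm]] / (1 - 0.9^step)
          vhat <- vv[[nm]] / (1 - 0.999^step)
          par[[nm]] <- par[[nm]] - spec$learning_rate * mhat /
            (sqrt(vhat) + 1e-8)
        }
      }
      ep_loss <- ep_loss / n
      if (ep_loss < best_loss - 1e-12) {
        best_loss <- ep_loss
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= spec$patience) break
      }
    }
  })
  pred <- vapply(seq_len(n),
                 function(j) lstm_forward(par, sup$inputs[j, ]), numeric(1))
  orig <- to_supervised(v, spec$lookback)
  mae <- mean(abs(inverse_scale(sc$transform, pred) - orig$targets))
  trained_regressor(kind = "lstm", fit = par, spec = spec,
                    transform = sc$transform, train_mae = mae,
                    hyper = list(units = spec$units, dropout = spec$dropout,
                                 batch_size = spec$batch_size))
}

#' @export
predict_one_step.lstm_regressor <- function(model, window, ...) {
  w <- matrix(window, ncol = model$lookback)
  vapply(seq_len(nrow(w)),
         function(i) lstm_forward(model$fit, w[i, ]), numeric(1))
}
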