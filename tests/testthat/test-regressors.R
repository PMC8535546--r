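# ---- windowing and scaling ---------------------------------------------

test_that("supervised conversion yields length - lookback aligned pairs", {
  sup <- to_supervised(1:10, lookback = 7)
  expect_equal(nrow(sup$inputs), 3L)
  expect_equal(sup$inputs[1, ], 1:7)
  expect_equal(sup$targets, 8:10)
  expect_equal(nrow(to_supervised(rep(0, 90))$inputs), 83L)
  expect_equal(nrow(to_supervised(rep(0, 120))$inputs), 113L)
  expect_error(to_supervised(1:7), "exceed")
})

test_that("min-max scaling round-trips, including degenerate series", {
  sc <- scale_series(c(0, 5, 10))
  expect_equal(sc$scaled, c(0, 0.5, 1))
  expect_equal(inverse_scale(sc$transform, sc$scaled), c(0, 5, 10))
  z <- scale_series(rep(0, 20))
  expect_equal(z$scaled, rep(0, 20))
  expect_equal(inverse_scale(z$transform, z$scaled), rep(0, 20))
  k <- scale_series(rep(42, 5))
  expect_equal(inverse_scale(k$transform, k$scaled), rep(42, 5))
  set.seed(3)
  v <- runif(60, 0, 2000)
  sc <- scale_series(v)
  expect_lt(max(abs(inverse_scale(sc$transform, sc$scaled) - v)), 1e-9)
})

# ---- SVR ----------------------------------------------------------------

test_that("SVR on a constant series predicts inside the 10-second tube", {
  fit <- fit_svr(rep(500, 40), svr_spec())
  f <- forecast_recursive(fit, rep(500, 40), horizon = 10)
  expect_true(all(abs(f - 500) <= 10))
  expect_equal(fit$train_mae, 0)
})

test_that("the fitted SVR objective matches a numeric primal minimisation", {
  # representer form on a 5-point toy: f(x) = K theta + b, objective
  # 0.5 theta' K theta + C sum(max(0, |resid| - eps))
  x <- matrix(c(0, 0.2, 0.45, 0.7, 1.0), ncol = 1)
  y <- c(0.1, 0.35, 0.4, 0.8, 0.95)
  gam <- 0.5; C <- 2; eps <- 0.1
  K <- exp(-gam * as.matrix(dist(x))^2)
  fit <- e1071::svm(x = x, y = y, type = "eps-regression", kernel = "radial",
                    gamma = gam, cost = C, epsilon = eps, scale = FALSE)
  theta <- rep(0, 5); theta[fit$index] <- fit$coefs
  fsvm <- as.numeric(K %*% theta) - fit$rho
  obj_svm <- 0.5 * sum(theta * (K %*% theta)) +
    C * sum(pmax(0, abs(y - fsvm) - eps))
  primal <- function(p) {
    f <- as.numeric(K %*% p[1:5]) + p[6]
    0.5 * sum(p[1:5] * (K %*% p[1:5])) + C * sum(pmax(0, abs(y - f) - eps))
  }
  set.seed(4)
  best <- Inf
  for (r in 1:20) {
    o <- optim(rnorm(6, 0, 0.5), primal, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-12))
    o <- optim(o$par, primal, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  expect_equal(obj_svm, best, tolerance = 1e-3)
})

test_that("SVR accepts all three kernels of the grid", {
  set.seed(10)
  v <- ifelse(runif(50) < .5, 0, runif(50, 100, 900))
  for (kern in c("polynomial", "radial", "sigmoid")) {
    fit <- fit_svr(v, svr_spec(kernel = kern, C = 10))
    expect_s3_class(fit, "trained_regressor")
    expect_gte(fit$train_mae, 0)
  }
})

# ---- LSTM ---------------------------------------------------------------

test_that("LSTM analytic gradients match central finite differences", {
  spec <- lstm_spec(units = 3, dropout = 0, batch_size = 1, lookback = 4)
  set.seed(11)
  par <- adherefit:::lstm_init(spec)
  # move every pre-activation off the ReLU kink at exactly zero, where the
  # subgradient and a central difference legitimately disagree
  par <- lapply(par, function(p) p + runif(length(p), 0.01, 0.2))
  xs <- runif(4)
  target <- 0.3
  fw <- adherefit:::lstm_forward(par, xs, keep_state = TRUE)
  gr <- adherefit:::lstm_backward(par, fw, target)
  h <- 1e-6
  for (nm in names(par)) {
    idx <- seq_len(min(4, length(par[[nm]])))
    for (j in idx) {
      pp <- par; pp[[nm]][j] <- pp[[nm]][j] + h
      pm <- par; pm[[nm]][j] <- pm[[nm]][j] - h
      lp <- 0.5 * (adherefit:::lstm_forward(pp, xs) - target)^2
      lm <- 0.5 * (adherefit:::lstm_forward(pm, xs) - target)^2
      num <- (lp - lm) / (2 * h)
      expect_equal(gr[[nm]][j], num, tolerance = 1e-4,
                   label = paste("grad", nm, j))
    }
  }
})

test_that("LSTM reproduces a constant series exactly after inverse scaling", {
  fit <- fit_lstm(rep(300, 30), lstm_spec(units = 4, epochs = 2), seed = 1)
  f <- forecast_recursive(fit, rep(300, 30), horizon = 5)
  expect_equal(f, rep(300, 5))  # degenerate transform restores the constant
})

test_that("LSTM learns a period-2 alternating signal better than the mean", {
  v <- rep(c(600, 0), 20)  # 40 days alternating
  wins <- 0
  for (seed in 1:5) {
    fit <- fit_lstm(v, lstm_spec(units = 12, dropout = 0, batch_size = 2,
                                 epochs = 40), seed = seed)
    baseline <- mean(abs(mean(v) - to_supervised(v)$targets))
    if (fit$train_mae < baseline) wins <- wins + 1
  }
  expect_gte(wins, 3)  # majority of seeds beat the constant-mean baseline
})

# ---- grid search and recursion -----------------------------------------

test_that("grid search returns the training-MAE minimiser", {
  v <- c(seq(100, 800, length.out = 45), seq(800, 100, length.out = 45))
  g1 <- svr_spec(kernel = "radial", C = 100)
  g2 <- svr_spec(kernel = "sigmoid", C = 1)
  pick <- grid_search_user(v, "svr", list(g1, g2))
  m1 <- fit_svr(v, g1); m2 <- fit_svr(v, g2)
  expect_equal(pick$train_mae, min(m1$train_mae, m2$train_mae))
  expect_lte(pick$train_mae, m1$train_mae)
  expect_lte(pick$train_mae, m2$train_mae)
  # singleton grid returns that model
  solo <- grid_search_user(v, "svr", list(g2))
  expect_equal(solo$hyper$kernel, "sigmoid")
  expect_error(grid_search_user(v, "svr", list()), "empty")
})

test_that("the default grids enumerate the documented combinations", {
  svr <- default_svr_grid()
  expect_length(svr, 18L)  # 3 kernels x 6 C values
  expect_equal(unique(vapply(svr, `[[`, character(1), "kernel")),
               c("polynomial", "radial", "sigmoid"))
  expect_true(all(vapply(svr, `[[`, numeric(1), "C") <= 500))
  lstm <- default_lstm_grid()
  expect_length(lstm, 45L)  # 3 dropout x 3 batch x 5 units
  expect_equal(sort(unique(vapply(lstm, `[[`, numeric(1), "dropout"))),
               c(0.2, 0.4, 0.6))
  expect_equal(sort(unique(vapply(lstm, `[[`, integer(1), "units"))),
               c(50L, 75L, 100L, 125L, 150L))
  expect_true(all(vapply(lstm, `[[`, integer(1), "epochs") == 50L))
})

test_that("recursive forecasting echoes stubs and never goes negative", {
  echo <- make_stub_echo()
  hist <- c(rep(0, 33), rep(1200, 7))  # last week constant at 1200 s
  f <- forecast_recursive(echo, hist, horizon = 30)
  expect_equal(f, rep(1200, 30))

  zero <- fit_svr(rep(0, 40), svr_spec())  # all-zero user
  expect_equal(forecast_recursive(zero, rep(0, 40)), rep(0, 30))

  set.seed(7)
  v <- ifelse(runif(60) < .4, 0, runif(60, 50, 1500))
  fit <- fit_svr(v, svr_spec(kernel = "radial", C = 10))
  f <- forecast_recursive(fit, v, horizon = 30)
  expect_length(f, 30L)
  expect_true(all(f >= 0))
  expect_error(forecast_recursive(fit, v[1:3]), "lookback")
})
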