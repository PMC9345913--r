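make_tsk_data <- function(model, n, seed = 1) {
  set.seed(seed)
  k <- length(model$inputs)
  X <- sapply(model$inputs, function(f)
    stats::runif(n, f$domain_min, f$domain_max))
  list(X = X, y = predict(model, X))
}

test_that("least squares recovers a realizable TSK model exactly", {
  truth <- random_small_anfis(2, 2, family = "gaussmf", seed = 31)
  dat <- make_tsk_data(truth, 300, seed = 32)
  blank <- truth
  blank$consequents <- matrix(0, nrow(truth$rules), 3)
  fitted <- lse_consequents(blank, dat$X, dat$y)
  expect_equal(fitted$consequents, truth$consequents, tolerance = 1e-7)
  expect_lt(rmse(dat$y, predict(fitted, dat$X)), 1e-9)
})

test_that("least squares yields zero consequents for a zero response", {
  m <- random_small_anfis(2, 2, seed = 33)
  dat <- make_tsk_data(m, 100, seed = 34)
  fitted <- lse_consequents(m, dat$X, rep(0, 100))
  expect_equal(max(abs(fitted$consequents)), 0, tolerance = 1e-10)
})

test_that("single-rule least squares reduces to ordinary regression", {
  s <- anfis(list(single_mf_input("x", c(0, 1))))
  set.seed(35)
  x <- stats::runif(50)
  y <- 2.5 * x - 0.7 + stats::rnorm(50, sd = 0.1)
  fitted <- lse_consequents(s, matrix(x), y)
  ols <- stats::coef(stats::lm(y ~ x))
  expect_equal(unname(fitted$consequents[1, ]),
               unname(ols[c("x", "(Intercept)")]), tolerance = 1e-8)
})

test_that("rank-deficient designs warn and return a finite solution", {
  m <- random_small_anfis(3, 3, seed = 36)
  X <- matrix(stats::runif(15, 0, 1), ncol = 3)
  X <- X[c(1:5, 1:5), ]   # duplicated rows force a deficient design
  y <- predict(m, X)      # realizable response: residual must vanish
  blank <- m; blank$consequents[] <- 0
  expect_warning(fitted <- lse_consequents(blank, X, y), "minimum-norm")
  expect_true(all(is.finite(fitted$consequents)))
  expect_lt(rmse(y, predict(fitted, X)), 1e-8)
})

test_that("an LSE pass never increases training error, premise frozen", {
  set.seed(37)
  for (i in 1:5) {
    m <- random_small_anfis(2, 2, family = "gbellmf", seed = 40 + i)
    X <- matrix(stats::runif(120, -1, 2), ncol = 2)
    y <- sin(X[, 1]) + 0.5 * X[, 2] + stats::rnorm(60, sd = 0.05)
    before <- sum((y - predict(m, X))^2)
    after <- sum((y - predict(lse_consequents(m, X, y), X))^2)
    expect_lte(after, before + 1e-10)
  }
})

test_that("analytic premise gradient matches finite differences", {
  for (fam in c("gaussmf", "gbellmf")) {
    m <- random_small_anfis(2, 2, family = fam, seed = 51)
    set.seed(52)
    X <- matrix(stats::runif(40, -0.5, 1.5), ncol = 2)
    y <- stats::rnorm(20)
    g <- anfisdry:::premise_gradient(m, X, y)
    th <- anfisdry:::premise_params(m)
    h <- 1e-6
    sse <- function(t) {
      mm <- anfisdry:::set_premise_params(m, t)
      sum((anfisdry:::forward_pass(mm, X)$y - y)^2)
    }
    fd <- vapply(seq_along(th), function(i) {
      tp <- th; tm <- th
      tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
      (sse(tp) - sse(tm)) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("premise step honours its contract at the boundaries", {
  m <- random_small_anfis(2, 2, seed = 53)
  X <- matrix(stats::runif(40), ncol = 2)
  # step 0 is the identity
  expect_identical(anfisdry:::premise_params(backprop_premise(m, X,
    stats::rnorm(20), 0)), anfisdry:::premise_params(m))
  # zero training error means zero gradient, parameters unchanged
  y_exact <- predict(m, X)
  stepped <- backprop_premise(m, X, y_exact, 0.1)
  expect_equal(anfisdry:::premise_params(stepped),
               anfisdry:::premise_params(m), tolerance = 1e-12)
})

test_that("the data split is seeded, disjoint and exhaustive", {
  cfg <- train_config(seed = 99)
  idx <- split_indices(222, cfg)
  expect_equal(sort(c(idx$train, idx$check, idx$test)), 1:222)
  expect_length(idx$train, floor(0.6 * 222))
  expect_length(idx$check, floor(0.15 * 222))
  expect_identical(split_indices(222, cfg), idx)
  expect_false(identical(split_indices(222, train_config(seed = 100)), idx))
  # split does not disturb the global RNG stream
  set.seed(1); a <- stats::runif(1)
  set.seed(1); invisible(split_indices(50, cfg)); b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("training converges on realizable data and selects the best epoch", {
  gen <- generate_drying_data(generator_config(noise_sd = 0))
  d <- gen$data
  cfg <- train_config(max_epochs = 15, seed = 2)
  fit <- suppressWarnings(
    anfis_train(drying_anfis(d, n_mf = 3), d, config = cfg))
  expect_equal(fit$best_epoch, which.min(fit$check_rmse))
  expect_lte(fit$best_epoch, cfg$max_epochs)
  # the snapshot reproduces the recorded checking RMSE on re-evaluation
  X <- d[, c("time_min", "temperature_C", "pretreatment_min")]
  yhat <- predict(fit$model, X)
  expect_equal(rmse(d$moisture_ratio[fit$split$check],
                    yhat[fit$split$check]),
               fit$check_rmse[fit$best_epoch], tolerance = 1e-12)
  # deterministic under the same seed
  fit2 <- suppressWarnings(
    anfis_train(drying_anfis(d, n_mf = 3), d, config = cfg))
  expect_identical(fit2$train_rmse, fit$train_rmse)
  expect_identical(fit2$check_rmse, fit$check_rmse)
  expect_identical(fit2$test_rmse, fit$test_rmse)
})

test_that("training error descends to near zero on a linear target", {
  # a linear response is realizable by any TSK rule base
  set.seed(61)
  d <- data.frame(time_min = runif(80, 0, 100),
                  temperature_C = runif(80, 50, 70),
                  pretreatment_min = runif(80, 0, 10))
  d$moisture_ratio <- 0.002 * d$time_min - 0.01 * d$temperature_C + 1
  cfg <- train_config(max_epochs = 8, seed = 3, ridge_slope = 0,
                      ridge_intercept = 0)
  fit <- suppressWarnings(anfis_train(drying_anfis(d, n_mf = 2), d,
                                      config = cfg))
  expect_lt(fit$train_rmse[1], 1e-8)
  expect_true(all(diff(fit$train_rmse) < 1e-8))
})

test_that("error metrics follow their definitions", {
  y <- c(0, 1, 2); yh <- c(0, 1, 1)
  expect_equal(rmse(y, yh), sqrt(1 / 3))
  expect_equal(rmse(y, y), 0)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_error(r_squared(c(1, 1), c(1, 2)), "constant")
  expect_error(train_config(max_epochs = 0), "max_epochs")
})
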