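# Short training runs: these tests exercise the grid and subset mechanics;
# predictive-quality checks at full training length live in the acceptance
# suite.

test_that("the structure grid evaluates every family-count cell once", {
  gen <- generate_drying_data(generator_config(seed = 4))
  gs <- suppressWarnings(
    run_grid(gen$data, config = train_config(max_epochs = 2, seed = 4)))
  expect_equal(nrow(gs$results), 12)
  expect_setequal(unique(gs$results$family),
                  c("trimf", "gbellmf", "gaussmf", "pimf"))
  expect_setequal(unique(gs$results$n_mf), c(2, 3, 5))
  expect_equal(gs$results$n_rules, gs$results$n_mf^3)
  ok <- !gs$results$failed
  expect_equal(max(gs$results$test_r2[ok]),
               gs$results$test_r2[gs$results$family == gs$best$family &
                                    gs$results$n_mf == gs$best$n_mf])
  # identical seed reproduces the grid exactly
  gs2 <- suppressWarnings(
    run_grid(gen$data, config = train_config(max_epochs = 2, seed = 4)))
  expect_identical(gs2$results, gs$results)
})

test_that("a failing structure is recorded without aborting the grid", {
  gen <- generate_drying_data(generator_config(seed = 4))
  d <- gen$data
  d$pretreatment_min <- 0   # constant factor: every structure degenerate
  expect_error(suppressWarnings(
    run_grid(d, config = train_config(max_epochs = 2))), "every structure")
})

test_that("sensitivity evaluates the three singletons and three pairs", {
  gen <- generate_drying_data(generator_config(seed = 4))
  rep <- suppressWarnings(run_sensitivity(
    gen$data, family = "gaussmf", n_mf = 2,
    config = train_config(max_epochs = 5, seed = 4)))
  expect_equal(nrow(rep$results), 6)
  expect_equal(sum(rep$results$n_factors == 1), 3)
  expect_equal(sum(rep$results$n_factors == 2), 3)
  # rankings are permutations consistent with the recorded RMSEs
  for (a in 1:2) {
    sub <- rep$results[rep$results$n_factors == a, ]
    expect_setequal(sub$rank_within_arity, 1:3)
    expect_equal(order(sub$rmse_full), order(sub$rank_within_arity))
  }
  # determinism
  rep2 <- suppressWarnings(run_sensitivity(
    gen$data, family = "gaussmf", n_mf = 2,
    config = train_config(max_epochs = 5, seed = 4)))
  expect_identical(rep2$results, rep$results)
})

test_that("a constant factor is flagged and excluded from the ranking", {
  gen <- generate_drying_data(generator_config(seed = 4))
  d <- gen$data
  d$pretreatment_min <- 3
  w <- capture_warnings(
    rep <- run_sensitivity(d, family = "gaussmf", n_mf = 2,
                           config = train_config(max_epochs = 3, seed = 4)))
  expect_equal(sum(grepl("constant factor", w)), 3)  # singleton + two pairs
  expect_true(any(rep$results$degenerate))
  expect_true(all(is.na(
    rep$results$rank_within_arity[rep$results$degenerate])))
})

test_that("time alone predicts a time-only response best", {
  # response depends on drying time only; other factors shuffled/irrelevant
  gen <- generate_drying_data(generator_config(noise_sd = 0))
  d <- gen$data
  set.seed(8)
  d$temperature_C <- sample(d$temperature_C)
  d$pretreatment_min <- sample(d$pretreatment_min)
  d$moisture_ratio <- exp(-0.01 * d$time_min)
  rep <- suppressWarnings(run_sensitivity(
    d, family = "gbellmf", n_mf = 3,
    config = train_config(max_epochs = 10, seed = 8)))
  singles <- rep$results[rep$results$n_factors == 1, ]
  expect_equal(singles$subset[which.min(singles$rmse_full)], "time_min")
})

test_that("adding a factor cannot worsen achievable training fit", {
  # noiseless data, exact LSE on the training partition: nested model classes
  gen <- generate_drying_data(generator_config(noise_sd = 0))
  d <- gen$data
  cfg <- train_config(seed = 9)
  idx <- split_indices(nrow(d), cfg)
  tr <- d[idx$train, ]
  fit_sse <- function(factors) {
    m <- drying_anfis(d, family = "gaussmf", n_mf = 2, factors = factors)
    m <- suppressWarnings(lse_consequents(
      m, tr[, factors, drop = FALSE], tr$moisture_ratio))
    sum((tr$moisture_ratio -
           predict(m, tr[, factors, drop = FALSE]))^2)
  }
  sse_t <- fit_sse("time_min")
  expect_lte(fit_sse(c("time_min", "temperature_C")), sse_t + 1e-8)
  expect_lte(fit_sse(c("time_min", "pretreatment_min")), sse_t + 1e-8)
})
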