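#' Build the ANFIS model for a drying dataset
#'
#' Constructs a Sugeno ANFIS over the drying factors (`time_min`,
#' `temperature_C`, `pretreatment_min` by default) with grid-partition
#' membership functions spanning each factor's observed range.
#'
#' @param data Long-format drying data frame.
#' @param family Membership family.
#' @param n_mf Membership functions per input.
#' @param factors Input columns to fuzzify.
#' @return An [anfis()] model.
#' @export
drying_anfis <- function(data, family = "gbellmf", n_mf = 3,
                         factors = c("time_min", "temperature_C",
                                     "pretreatment_min")) {
  data <- validate_drying_data(data)
  inputs <- lapply(factors, function(f) {
    fuzzy_input(f, range(data[[f]]), n_mf = n_mf, family = family)
  })
  anfis(inputs)
}

#' Structure search over membership family and count
#'
#' Trains one ANFIS per cell of the structure grid — the four membership
#' families (trimf, pimf, gbellmf, gaussmf) crossed with 2, 3 and 5
#' membership functions per input — using an identical data split (same
#' seed) in every cell, so performance differences reflect structure alone.
#' The winning structure is the one with the highest test-partition R^2;
#' ties break toward fewer rules, then toward the earlier best epoch.
#'
#' @param data Long-format drying data frame with the three drying factors
#'   and `moisture_ratio`.
#' @param config A [train_config()].
#' @param families Membership families to try.
#' @param n_mfs Membership counts to try.
#' @param factors Input columns.
#' @param response Response column.
#' @return A `grid_search_result`: `results` (one row per structure:
#'   `family`, `n_mf`, `n_rules`, `best_epoch`, `test_r2`, `test_rmse`,
#'   `failed`), `best` (list `family`, `n_mf`), `best_fit` (the winning
#'   `train_result`).
#' @export
run_grid <- function(data, config = train_config(),
                     families = c("trimf", "gbellmf", "gaussmf", "pimf"),
                     n_mfs = c(2, 3, 5),
                     factors = c("time_min", "temperature_C",
                                 "pretreatment_min"),
                     response = "moisture_ratio") {
  data <- validate_drying_data(data)
  grid <- expand.grid(family = families, n_mf = n_mfs,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fam <- grid$family[i]; m <- grid$n_mf[i]
    res <- tryCatch({
      model <- drying_anfis(data, family = fam, n_mf = m, factors = factors)
      fit <- anfis_train(model, data, response = response, config = config)
      fits[[i]] <<- fit
      data.frame(family = fam, n_mf = m, n_rules = m^length(factors),
                 best_epoch = fit$best_epoch, test_r2 = fit$test_r2,
                 test_rmse = fit$test_rmse, failed = FALSE)
    }, error = function(e) {
      warning(sprintf("structure %s/%d failed: %s", fam, m,
                      conditionMessage(e)), call. = FALSE)
      data.frame(family = fam, n_mf = m, n_rules = m^length(factors),
                 best_epoch = NA_integer_, test_r2 = NA_real_,
                 test_rmse = NA_real_, failed = TRUE)
    })
    res
  })
  results <- do.call(rbind, rows)
  ok <- which(!results$failed & is.finite(results$test_r2))
  if (length(ok) == 0) stop("every structure failed to train", call. = FALSE)
  ord <- ok[order(-results$test_r2[ok], results$n_rules[ok],
                  results$best_epoch[ok])]
  best_i <- ord[1]
  structure(list(results = results,
                 best = list(family = results$family[best_i],
                             n_mf = results$n_mf[best_i]),
                 best_fit = fits[[best_i]],
                 factors = factors, response = response, config = config),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("ANFIS structure search\n")
  print(x$results, row.names = FALSE)
  cat(sprintf("best: %s with %d mfs (test R2 %.4f)\n", x$best$family,
              x$best$n_mf, x$results$test_r2[
                x$results$family == x$best$family &
                  x$results$n_mf == x$best$n_mf]))
  invisible(x)
}
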