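#' Construct a first-order Takagi-Sugeno ANFIS model
#'
#' Builds a Sugeno fuzzy inference system over a set of fuzzy inputs with a
#' full grid rule base: one rule per combination of membership functions, the
#' Cartesian product across inputs, so a model with k inputs of m membership
#' functions each carries m^k rules. Each rule's consequent is a first-order
#' polynomial `f_i = p_i1 x_1 + ... + p_ik x_k + r_i` in the crisp inputs.
#'
#' @param inputs List of [fuzzy_input()] objects (at least one).
#' @param min_firing Underflow floor applied to the rule-strength sum before
#'   normalization, guarding against 0/0 at extreme extrapolation.
#' @return An `anfis` object with fields `inputs`, `rules` (rule-by-input
#'   matrix of membership indices), `consequents` (rules x (k+1) matrix,
#'   initialised to zero) and `min_firing`.
#' @export
anfis <- function(inputs, min_firing = 1e-12) {
  stopifnot(is.list(inputs), length(inputs) >= 1,
            all(vapply(inputs, inherits, logical(1), "fuzzy_input")))
  k <- length(inputs)
  m <- vapply(inputs, function(f) length(f$mfs), integer(1))
  rules <- as.matrix(do.call(expand.grid, lapply(m, seq_len)))
  dimnames(rules) <- list(NULL, vapply(inputs, `[[`, character(1), "name"))
  structure(
    list(inputs = inputs, rules = rules,
         consequents = matrix(0, nrow(rules), k + 1),
         min_firing = min_firing, trained = FALSE),
    class = "anfis")
}

#' @export
print.anfis <- function(x, ...) {
  m <- vapply(x$inputs, function(f) length(f$mfs), integer(1))
  fam <- vapply(x$inputs, `[[`, character(1), "family")
  cat(sprintf("Sugeno ANFIS: %d input(s), %s mfs (%s), %d rules%s\n",
              length(x$inputs), paste(m, collapse = "x"),
              paste(unique(fam), collapse = ","), nrow(x$rules),
              if (isTRUE(x$trained)) ", trained" else ""))
  invisible(x)
}

as_input_matrix <- function(model, x) {
  k <- length(model$inputs)
  if (is.data.frame(x)) {
    nms <- vapply(model$inputs, `[[`, character(1), "name")
    if (!all(nms %in% names(x))) {
      stop("input data lacks column(s): ",
           paste(setdiff(nms, names(x)), collapse = ", "), call. = FALSE)
    }
    x <- as.matrix(x[, nms, drop = FALSE])
  } else if (is.null(dim(x))) {
    if (length(x) != k) stop("x_vector length must equal number of inputs",
                             call. = FALSE)
    x <- matrix(x, nrow = 1)
  }
  if (ncol(x) != k) stop("input matrix must have one column per fuzzy input",
                         call. = FALSE)
  x
}

# Membership degrees per input: list of n x m_j matrices.
membership_layers <- function(model, X) {
  lapply(seq_along(model$inputs), function(j) {
    vapply(model$inputs[[j]]$mfs, eval_mf, numeric(nrow(X)), x = X[, j])
  })
}

#' Rule firing strengths
#'
#' Layer-3 product t-norm: each rule's strength is the product of its
#' membership degrees across the model's inputs.
#'
#' @param model An [anfis()] model.
#' @param x One input vector, an input matrix (rows = observations), or a
#'   data frame carrying the model's input columns.
#' @return Matrix of non-negative firing strengths, observations x rules.
#' @export
firing_strengths <- function(model, x) {
  X <- as_input_matrix(model, x)
  mu <- lapply(seq_along(model$inputs), function(j) {
    m <- vapply(model$inputs[[j]]$mfs, eval_mf, numeric(nrow(X)), x = X[, j])
    if (!is.matrix(m)) m <- matrix(m, nrow = nrow(X))
    m
  })
  W <- matrix(1, nrow(X), nrow(model$rules))
  for (j in seq_along(mu)) {
    W <- W * mu[[j]][, model$rules[, j], drop = FALSE]
  }
  W
}

#' Normalize firing strengths
#'
#' Layer-4 normalization: each rule's strength divided by the sum over all
#' rules, so the normalized strengths form convex weights.
#'
#' @param w Numeric vector (one observation) or matrix (rows = observations)
#'   of non-negative firing strengths.
#' @param min_firing Underflow floor on the row sums; a row whose strengths
#'   sum to at or below this is degenerate.
#' @return Same shape as `w`, rows summing to 1.
#' @export
normalize_firing <- function(w, min_firing = 1e-12) {
  vec <- is.null(dim(w))
  if (vec) w <- matrix(w, nrow = 1)
  s <- rowSums(w)
  bad <- !is.finite(s) | s <= min_firing
  if (any(bad)) {
    stop(sprintf("degenerate input: all rule firing strengths ~0 for row(s) %s",
                 paste(utils::head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  }
  out <- w / s
  if (vec) out[1, ] else out
}

# Forward pass pieces shared by predict / training. Floors the strength sum
# (rather than erroring) so training is robust at extrapolated points.
forward_pass <- function(model, X) {
  W <- firing_strengths(model, X)
  S <- pmax(rowSums(W), model$min_firing)
  Wbar <- W / S
  Xa <- cbind(X, 1)
  F <- Xa %*% t(model$consequents)   # n x rules, per-rule linear outputs
  list(W = W, S = S, Wbar = Wbar, F = F, Xa = Xa,
       y = rowSums(Wbar * F))
}

#' Predict from an ANFIS model
#'
#' Layers 5-6: the output is the firing-strength-weighted sum of the rule
#' consequents, \eqn{\hat y = \sum_i \bar w_i (p_i x + ... + r_i)}.
#'
#' @param object An [anfis()] model.
#' @param newdata Input vector, matrix or data frame.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.anfis <- function(object, newdata, ...) {
  X <- as_input_matrix(object, newdata)
  unname(forward_pass(object, X)$y)
}

# Per-rule premise centers (rules x inputs): each rule's membership centers,
# used to express consequents in locally-centered coordinates.
rule_centers <- function(model) {
  centers <- lapply(model$inputs, function(f) {
    vapply(f$mfs, function(m) {
      p <- m$params
      switch(m$family,
             gbellmf = p[["c"]], gaussmf = p[["c"]], trimf = p[["b"]],
             pimf = (p[["b"]] + p[["c"]]) / 2)
    }, numeric(1))
  })
  matrix(vapply(seq_along(centers), function(j)
    centers[[j]][model$rules[, j]], numeric(nrow(model$rules))),
    nrow = nrow(model$rules))
}

input_widths <- function(model) {
  vapply(model$inputs, function(f) f$domain_max - f$domain_min, numeric(1))
}

#' Least-squares estimation of the consequent parameters
#'
#' With the premise (membership) parameters frozen, the ANFIS output is
#' linear in the consequent coefficients, so they are fitted in one pass of
#' linear least squares on the design matrix of normalized firing strengths
#' times augmented inputs. The solve works in rule-centered, domain-scaled
#' coordinates (each rule's linear term measured from its own membership
#' centers, per input-domain width) for numerical balance, and uses singular
#' value decomposition — a pseudo-inverse, not normal equations. Rank
#' deficiency yields the minimum-norm solution with a warning.
#'
#' With positive ridge penalties the solve becomes Tikhonov-regularized:
#' slope coefficients shrink toward zero and each rule's intercept shrinks
#' toward the rule's exposure-weighted local mean of `y`. This leaves
#' well-determined coefficients essentially untouched but pins down rules
#' with little training exposure, which would otherwise be free to take
#' arbitrarily large values along near-null directions of the design and
#' wreck interpolation between training points. Training uses small nonzero
#' penalties by default (see [train_config()]); the default here is the
#' exact, unregularized least-squares solution.
#'
#' @param model An [anfis()] model.
#' @param X Input matrix or data frame (rows = training observations).
#' @param y Numeric response vector.
#' @param ridge_slope,ridge_intercept Non-negative Tikhonov penalties on the
#'   scaled slope and intercept coefficients; 0 = plain least squares.
#' @param warn_rank Warn when the unregularized design is rank deficient.
#' @return The model with updated `consequents`.
#' @export
lse_consequents <- function(model, X, y, ridge_slope = 0,
                            ridge_intercept = 0, warn_rank = TRUE) {
  X <- as_input_matrix(model, X)
  stopifnot(nrow(X) == length(y), ridge_slope >= 0, ridge_intercept >= 0)
  fp <- forward_pass(model, X)
  k <- ncol(X)
  k1 <- k + 1
  R <- nrow(model$rules)
  wj <- input_widths(model)
  Cn <- rule_centers(model)
  D <- matrix(0, nrow(X), R * k1)
  for (i in seq_len(R)) {
    Z <- sweep(sweep(X, 2, Cn[i, ]), 2, wj, "/")
    D[, (i - 1) * k1 + seq_len(k1)] <- fp$Wbar[, i] * cbind(Z, 1)
  }
  if (ridge_slope == 0 && ridge_intercept == 0) {
    sv <- svd(D)
    tol <- max(dim(D)) * max(sv$d) * .Machine$double.eps
    pos <- sv$d > tol
    if (warn_rank && sum(pos) < min(dim(D))) {
      warning(sprintf("rank-deficient consequent design (rank %d of %d): using minimum-norm solution",
                      sum(pos), min(dim(D))), call. = FALSE)
    }
    theta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  } else {
    expo <- colSums(fp$Wbar)
    local_mean <- ifelse(expo > 1e-8, colSums(fp$Wbar * y) / pmax(expo, 1e-8),
                         mean(y))
    target <- rep(0, R * k1)
    target[seq(k1, R * k1, by = k1)] <- local_mean
    pen <- rep(c(rep(sqrt(ridge_slope), k), sqrt(ridge_intercept)), R)
    Daug <- rbind(D, diag(pen))
    yaug <- c(y - D %*% target, rep(0, R * k1))
    sv <- svd(Daug)
    pos <- sv$d > max(dim(Daug)) * max(sv$d) * .Machine$double.eps
    theta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], yaug)) / sv$d[pos]) + target
  }
  Cq <- matrix(0, R, k1)
  for (i in seq_len(R)) {
    b <- theta[(i - 1) * k1 + seq_len(k1)]
    p_raw <- b[seq_len(k)] / wj
    Cq[i, ] <- c(p_raw, b[k1] - sum(p_raw * Cn[i, ]))
  }
  model$consequents <- Cq
  model
}

# Flatten/unflatten premise parameters for gradient bookkeeping.
premise_params <- function(model) {
  unlist(lapply(model$inputs, function(f) {
    lapply(f$mfs, function(m) m$params)
  }))
}

set_premise_params <- function(model, theta) {
  idx <- 1L
  for (j in seq_along(model$inputs)) {
    for (l in seq_along(model$inputs[[j]]$mfs)) {
      mf <- model$inputs[[j]]$mfs[[l]]
      np <- length(mf$params)
      raw <- theta[idx:(idx + np - 1L)]
      names(raw) <- names(mf$params)
      mf$params <- mf_project(mf$family, raw)
      model$inputs[[j]]$mfs[[l]] <- mf
      idx <- idx + np
    }
  }
  model
}

# Analytic gradient of the training SSE with respect to every premise
# parameter (same ordering as premise_params). Non-finite elements zeroed.
premise_gradient <- function(model, X, y) {
  fp <- forward_pass(model, X)
  resid <- fp$y - y
  # dSSE/dw_i = 2 resid * (F_i - yhat) / S
  G <- (2 * resid / fp$S) * (fp$F - fp$y)   # n x rules
  grads <- list()
  for (j in seq_along(model$inputs)) {
    muj <- vapply(model$inputs[[j]]$mfs, eval_mf, numeric(nrow(X)),
                  x = X[, j])
    if (!is.matrix(muj)) muj <- matrix(muj, nrow = nrow(X))
    mu_rule <- muj[, model$rules[, j], drop = FALSE]
    # product of the other inputs' degrees: w_i / mu_(j, rule i)
    PE <- ifelse(mu_rule > 0, fp$W / mu_rule, 0)
    for (l in seq_along(model$inputs[[j]]$mfs)) {
      use <- which(model$rules[, j] == l)
      acc <- rowSums((G * PE)[, use, drop = FALSE])
      dmu <- mf_grad(model$inputs[[j]]$mfs[[l]], X[, j])
      g <- colSums(acc * dmu)
      g[!is.finite(g)] <- 0
      grads[[length(grads) + 1L]] <- g
    }
  }
  unlist(grads)
}

#' One gradient-descent step on the premise parameters
#'
#' Backpropagation half of the hybrid learning rule: a single full-batch
#' steepest-descent step on the training sum of squared errors with respect
#' to all membership-function parameters, with the consequents frozen. The
#' update moves a distance `step` along the negative normalized gradient
#' (the classic ANFIS step-size convention); parameter validity is restored
#' by projection afterwards. Kinks of the piecewise-linear families use the
#' zero subgradient; non-finite gradient elements are zeroed.
#'
#' The gradient is preconditioned by each input's domain width (equivalent to
#' taking the step in domain-normalized parameter coordinates), so inputs
#' measured on very different scales — drying time in hundreds of minutes
#' against blanching time in single minutes — adapt at comparable rates.
#' `step` is therefore a fraction of the input domain per epoch.
#'
#' @param model An [anfis()] model.
#' @param X Input matrix or data frame.
#' @param y Response vector.
#' @param step Step length in domain-normalized parameter space; `0` returns
#'   the model unchanged.
#' @return The model with updated premise parameters.
#' @export
backprop_premise <- function(model, X, y, step) {
  X <- as_input_matrix(model, X)
  if (step == 0) return(model)
  scales <- unlist(lapply(model$inputs, function(f) {
    w <- f$domain_max - f$domain_min
    unlist(lapply(f$mfs, function(m) rep(w, length(m$params))))
  }))
  g <- premise_gradient(model, X, y) * scales
  gn <- sqrt(sum(g^2))
  if (gn == 0) return(model)
  set_premise_params(model, premise_params(model) - step * (g / gn) * scales)
}

#' Root mean square error
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#' @return RMSE.
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SSE/SST}. The squared Pearson correlation variant is
#' available via `method = "corr"`.
#'
#' @param y Observed values (at least 2 distinct).
#' @param yhat Predicted values.
#' @param method `"sse"` (default, 1 - SSE/SST) or `"corr"` (squared
#'   correlation).
#' @return R-squared.
#' @export
r_squared <- function(y, yhat, method = c("sse", "corr")) {
  method <- match.arg(method)
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  if (stats::var(y) == 0) {
    stop("R-squared undefined for constant observed values", call. = FALSE)
  }
  if (method == "corr") return(stats::cor(y, yhat)^2)
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Training configuration
#'
#' @param max_epochs Number of hybrid training epochs.
#' @param initial_step Initial premise gradient step length.
#' @param step_increase Factor applied after 4 consecutive training-error
#'   decreases.
#' @param step_decrease Factor applied after an up-down-up-down oscillation.
#' @param split Train/check/test fractions, summing to 1.
#' @param seed Integer seed controlling the data shuffle.
#' @param min_firing Underflow floor for normalization.
#' @param ridge_slope,ridge_intercept Tikhonov penalties used by the
#'   consequent least-squares pass during training (see
#'   [lse_consequents()]); small nonzero defaults keep rules with little
#'   training exposure pinned to their local mean instead of exploding along
#'   near-null design directions.
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 100, initial_step = 0.02,
                         step_increase = 1.1, step_decrease = 0.9,
                         split = c(0.60, 0.15, 0.25), seed = 1,
                         min_firing = 1e-12,
                         ridge_slope = 1e-3, ridge_intercept = 1e-3) {
  stopifnot(length(split) == 3, all(split >= 0),
            abs(sum(split) - 1) < 1e-8)
  if (max_epochs < 1) stop("max_epochs must be >= 1", call. = FALSE)
  stopifnot(ridge_slope >= 0, ridge_intercept >= 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 initial_step = initial_step,
                 step_increase = step_increase,
                 step_decrease = step_decrease,
                 split = split, seed = as.integer(seed),
                 min_firing = min_firing,
                 ridge_slope = ridge_slope,
                 ridge_intercept = ridge_intercept),
            class = "train_config")
}

#' Split observation indices into train/check/test partitions
#'
#' Uniform random shuffle under the configuration seed, then contiguous
#' slices of the shuffled order at the configured fractions.
#'
#' @param n Number of observations.
#' @param config A [train_config()].
#' @return List of integer index vectors `train`, `check`, `test`.
#' @export
split_indices <- function(n, config) {
  old <- .Random.seed_save()
  set.seed(config$seed)
  perm <- sample.int(n)
  .Random.seed_restore(old)
  n_train <- floor(config$split[1] * n)
  n_check <- floor(config$split[2] * n)
  list(train = perm[seq_len(n_train)],
       check = perm[n_train + seq_len(n_check)],
       test = perm[setdiff(seq_len(n), seq_len(n_train + n_check))])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Hybrid ANFIS training with checking-set epoch selection
#'
#' Per epoch: exact least-squares fit of the consequents (premise frozen),
#' evaluation of training and checking RMSE, then one gradient step on the
#' premise parameters. The returned model is the snapshot at the epoch with
#' the lowest checking RMSE (first occurrence on ties) — the classic guard
#' against over-fitting, where the checking error falls and then rises again
#' as training proceeds. Test metrics are computed only on the held-out test
#' partition with that snapshot.
#'
#' @param model An [anfis()] model.
#' @param data Data frame containing the model's input columns and the
#'   response.
#' @param response Name of the response column.
#' @param config A [train_config()].
#' @return A `train_result` list: `train_rmse`, `check_rmse` (per-epoch
#'   trajectories), `best_epoch`, `model` (snapshot at best epoch),
#'   `test_rmse`, `test_r2`, `test_r2_corr`, `split` (index partitions),
#'   `config`.
#' @export
anfis_train <- function(model, data, response = "moisture_ratio",
                        config = train_config()) {
  stopifnot(inherits(model, "anfis"), inherits(config, "train_config"),
            response %in% names(data))
  model$min_firing <- config$min_firing
  X <- as_input_matrix(model, data)
  y <- data[[response]]
  idx <- split_indices(nrow(X), config)
  Xtr <- X[idx$train, , drop = FALSE]; ytr <- y[idx$train]
  Xck <- X[idx$check, , drop = FALSE]; yck <- y[idx$check]
  has_check <- length(idx$check) > 0

  step <- config$initial_step
  train_rmse <- check_rmse <- numeric(config$max_epochs)
  best <- Inf; best_epoch <- NA_integer_; best_model <- model
  decr_run <- 0L; osc_run <- 0L; prev_err <- Inf; prev_delta <- 0

  for (epoch in seq_len(config$max_epochs)) {
    model <- lse_consequents(model, Xtr, ytr,
                             ridge_slope = config$ridge_slope,
                             ridge_intercept = config$ridge_intercept,
                             warn_rank = epoch == 1)
    err_tr <- rmse(ytr, forward_pass(model, Xtr)$y)
    err_ck <- if (has_check) rmse(yck, forward_pass(model, Xck)$y) else err_tr
    train_rmse[epoch] <- err_tr
    check_rmse[epoch] <- err_ck
    if (err_ck < best) {
      best <- err_ck
      best_epoch <- epoch
      best_model <- model
    }
    # step-size heuristic: grow on sustained descent, shrink on oscillation
    if (epoch > 1) {
      delta <- err_tr - prev_err
      if (delta < 0) decr_run <- decr_run + 1L else decr_run <- 0L
      if (isTRUE(delta * prev_delta < 0)) osc_run <- osc_run + 1L
      else if (isTRUE(delta * prev_delta > 0)) osc_run <- 0L
      if (decr_run >= 4L) { step <- step * config$step_increase; decr_run <- 0L }
      if (osc_run >= 2L)  { step <- step * config$step_decrease; osc_run <- 0L }
      prev_delta <- delta
    }
    prev_err <- err_tr
    if (epoch < config$max_epochs) {
      model <- backprop_premise(model, Xtr, ytr, step)
    }
  }
  best_model$trained <- TRUE

  res <- list(train_rmse = train_rmse, check_rmse = check_rmse,
              best_epoch = best_epoch, model = best_model,
              split = idx, config = config,
              test_rmse = NA_real_, test_r2 = NA_real_,
              test_r2_corr = NA_real_)
  if (length(idx$test) >= 2) {
    yhat <- forward_pass(best_model, X[idx$test, , drop = FALSE])$y
    res$test_rmse <- rmse(y[idx$test], yhat)
    if (stats::var(y[idx$test]) > 0) {
      res$test_r2 <- r_squared(y[idx$test], yhat)
      res$test_r2_corr <- r_squared(y[idx$test], yhat, method = "corr")
    }
  }
  class(res) <- "train_result"
  res
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("ANFIS training: %d epoch(s), best epoch %d (check RMSE %.5g)\n",
              length(x$train_rmse), x$best_epoch,
              x$check_rmse[x$best_epoch]))
  if (is.finite(x$test_rmse)) {
    cat(sprintf("  test RMSE %.5g, test R2 %.5g\n", x$test_rmse, x$test_r2))
  }
  invisible(x)
}

#' Serialize an ANFIS model to JSON
#'
#' Writes family names, parameter vectors, the consequent matrix and domain
#' metadata to a JSON string (or file) that [anfis_from_json()] restores
#' exactly.
#'
#' @param model An [anfis()] model.
#' @param path Optional file path; when given, writes there and returns it
#'   invisibly.
#' @return JSON string, or `path` invisibly.
#' @export
anfis_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "anfis"))
  obj <- list(
    inputs = lapply(model$inputs, function(f) {
      list(name = f$name, family = f$family,
           domain = c(f$domain_min, f$domain_max),
           mfs = lapply(f$mfs, function(m)
             list(family = m$family, params = as.list(m$params))))
    }),
    consequents = model$consequents,
    min_firing = model$min_firing,
    trained = isTRUE(model$trained))
  js <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  js
}

#' Restore an ANFIS model from JSON
#' @param json JSON string or path to a file written by [anfis_to_json()].
#' @return An `anfis` model.
#' @export
anfis_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  inputs <- lapply(obj$inputs, function(f) {
    mfs <- lapply(f$mfs, function(m) {
      new_mf(m$family, unlist(m$params))
    })
    structure(list(name = f$name, domain_min = f$domain[[1]],
                   domain_max = f$domain[[2]], mfs = mfs,
                   family = f$family),
              class = "fuzzy_input")
  })
  model <- anfis(inputs, min_firing = obj$min_firing)
  cq <- do.call(rbind, lapply(obj$consequents, unlist))
  model$consequents <- matrix(as.numeric(cq), nrow = nrow(model$rules))
  model$trained <- isTRUE(obj$trained)
  model
}
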