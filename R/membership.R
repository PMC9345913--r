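#' Membership function constructors
#'
#' Builds a fuzzy membership function of one of the four standard families:
#' triangular (`trimf`), Gaussian (`gaussmf`), generalized bell (`gbellmf`)
#' or spline-based Pi curve (`pimf`). Parameter validity (ordering, positive
#' widths) is enforced at construction time so evaluation never fails.
#'
#' Definitions: `trimf(a,b,c)` rises linearly from a to its apex b and falls
#' to c; `gaussmf(sigma,c)` is `exp(-(x-c)^2 / (2 sigma^2))`;
#' `gbellmf(a,b,c)` is `1 / (1 + |(x-c)/a|^(2b))`; `pimf(a,b,c,d)` is the
#' product of an S-shaped spline rising over [a,b] and a Z-shaped spline
#' falling over [c,d].
#'
#' @param a,b,c,d,sigma Family-specific shape parameters (see Details).
#' @return An object of class `mf` with fields `family` and `params`.
#' @name membership
NULL

#' @rdname membership
#' @export
mf_tri <- function(a, b, c) {
  if (!(a <= b && b <= c)) stop("trimf requires a <= b <= c", call. = FALSE)
  if (a == c) stop("trimf requires a < c (non-degenerate support)", call. = FALSE)
  new_mf("trimf", c(a = a, b = b, c = c))
}

#' @rdname membership
#' @export
mf_gauss <- function(sigma, c) {
  if (sigma <= 0) stop("gaussmf requires sigma > 0", call. = FALSE)
  new_mf("gaussmf", c(sigma = sigma, c = c))
}

#' @rdname membership
#' @export
mf_gbell <- function(a, b, c) {
  if (a <= 0 || b <= 0) stop("gbellmf requires a > 0 and b > 0", call. = FALSE)
  new_mf("gbellmf", c(a = a, b = b, c = c))
}

#' @rdname membership
#' @export
mf_pi <- function(a, b, c, d) {
  if (!(a <= b && b <= c && c <= d)) {
    stop("pimf requires a <= b <= c <= d", call. = FALSE)
  }
  if (a == b || c == d) {
    stop("pimf requires a < b and c < d (non-degenerate shoulders)",
         call. = FALSE)
  }
  new_mf("pimf", c(a = a, b = b, c = c, d = d))
}

new_mf <- function(family, params) {
  structure(list(family = family, params = params), class = "mf")
}

#' @export
print.mf <- function(x, ...) {
  cat(sprintf("%s(%s)\n", x$family,
              paste(sprintf("%s=%g", names(x$params), x$params),
                    collapse = ", ")))
  invisible(x)
}

# S-shaped spline, 0 at a rising to 1 at b (MATLAB smf convention)
smf_eval <- function(x, a, b) {
  mid <- (a + b) / 2
  y <- numeric(length(x))
  y[x >= b] <- 1
  i <- x > a & x <= mid
  y[i] <- 2 * ((x[i] - a) / (b - a))^2
  i <- x > mid & x < b
  y[i] <- 1 - 2 * ((x[i] - b) / (b - a))^2
  y
}

# Z-shaped spline, 1 at a falling to 0 at b
zmf_eval <- function(x, a, b) 1 - smf_eval(x, a, b)

#' Evaluate a membership function
#'
#' @param mf An `mf` object from one of the constructors in [membership].
#' @param x Numeric vector of crisp input values.
#' @return Membership degrees in \[0, 1\], same length as `x`.
#' @export
eval_mf <- function(mf, x) {
  stopifnot(inherits(mf, "mf"))
  p <- mf$params
  switch(mf$family,
    trimf = {
      a <- p[["a"]]; b <- p[["b"]]; c <- p[["c"]]
      up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
      dn <- if (c > b) (c - x) / (c - b) else as.numeric(x <= b)
      pmax(pmin(up, dn, 1), 0)
    },
    gaussmf = exp(-(x - p[["c"]])^2 / (2 * p[["sigma"]]^2)),
    gbellmf = 1 / (1 + abs((x - p[["c"]]) / p[["a"]])^(2 * p[["b"]])),
    pimf = smf_eval(x, p[["a"]], p[["b"]]) * zmf_eval(x, p[["c"]], p[["d"]]),
    stop("unknown membership family: ", mf$family)
  )
}

# Analytic gradient of the membership degree with respect to each shape
# parameter, evaluated at x. Returns length(x) x n_params matrix. Kinks of
# the piecewise families use the zero one-sided subgradient.
mf_grad <- function(mf, x) {
  p <- mf$params
  n <- length(x)
  switch(mf$family,
    gaussmf = {
      s <- p[["sigma"]]; c <- p[["c"]]
      mu <- exp(-(x - c)^2 / (2 * s^2))
      cbind(sigma = mu * (x - c)^2 / s^3,
            c     = mu * (x - c) / s^2)
    },
    gbellmf = {
      a <- p[["a"]]; b <- p[["b"]]; c <- p[["c"]]
      t <- (x - c) / a
      u <- abs(t)^(2 * b)
      mu <- 1 / (1 + u)
      # d(mu)/d(theta) = -mu^2 * du/d(theta)
      da <- mu^2 * 2 * b * u / a
      dc <- ifelse(x == c, 0, mu^2 * 2 * b * u / (x - c))
      db <- ifelse(u == 0, 0, -mu^2 * 2 * u * log(pmax(abs(t), 1e-300)))
      cbind(a = da, b = db, c = dc)
    },
    trimf = {
      a <- p[["a"]]; b <- p[["b"]]; c <- p[["c"]]
      g <- matrix(0, n, 3, dimnames = list(NULL, c("a", "b", "c")))
      if (b > a) {
        i <- x > a & x < b
        g[i, "a"] <- (x[i] - b) / (b - a)^2
        g[i, "b"] <- -(x[i] - a) / (b - a)^2
      }
      if (c > b) {
        i <- x > b & x < c
        g[i, "b"] <- (c - x[i]) / (c - b)^2
        g[i, "c"] <- (x[i] - b) / (c - b)^2
      }
      g
    },
    pimf = {
      a <- p[["a"]]; b <- p[["b"]]; c <- p[["c"]]; d <- p[["d"]]
      s <- smf_eval(x, a, b)
      z <- zmf_eval(x, c, d)
      gs <- smf_grad(x, a, b)       # n x 2 (d/da, d/db)
      gz <- -smf_grad(x, c, d)      # zmf = 1 - smf
      cbind(a = z * gs[, 1], b = z * gs[, 2],
            c = s * gz[, 1], d = s * gz[, 2])
    },
    stop("unknown membership family: ", mf$family)
  )
}

smf_grad <- function(x, a, b) {
  mid <- (a + b) / 2
  ga <- numeric(length(x)); gb <- numeric(length(x))
  i <- x > a & x <= mid
  if (any(i)) {
    u <- (x[i] - a) / (b - a)
    ga[i] <- 4 * u * (x[i] - b) / (b - a)^2
    gb[i] <- 4 * u * -(x[i] - a) / (b - a)^2
  }
  i <- x > mid & x < b
  if (any(i)) {
    v <- (x[i] - b) / (b - a)
    ga[i] <- -4 * v * (x[i] - b) / (b - a)^2
    gb[i] <- -4 * v * (a - x[i]) / (b - a)^2
  }
  cbind(ga, gb)
}

# Project possibly-invalid parameters back into the family's feasible set
# after a gradient step.
mf_project <- function(family, params, eps = 1e-8) {
  switch(family,
    gaussmf = c(sigma = max(params[["sigma"]], eps), c = params[["c"]]),
    gbellmf = c(a = max(params[["a"]], eps), b = max(params[["b"]], eps),
                c = params[["c"]]),
    trimf = {
      s <- sort(unname(params[1:3]))
      if (s[3] - s[1] < eps) s[3] <- s[1] + eps
      c(a = s[1], b = s[2], c = s[3])
    },
    pimf = {
      s <- sort(unname(params[1:4]))
      if (s[2] - s[1] < eps) s[2] <- s[1] + eps
      if (s[4] - s[3] < eps) s[4] <- s[3] + eps
      c(a = s[1], b = s[2], c = s[3], d = s[4])
    },
    stop("unknown membership family: ", family)
  )
}

# Grid-partition initialization: m mfs with centers equally spaced over
# [lo, hi] and widths chosen so adjacent mfs cross near degree 0.5.
grid_partition_mfs <- function(family, m, lo, hi) {
  stopifnot(m >= 2, hi > lo)
  centers <- seq(lo, hi, length.out = m)
  h <- (hi - lo) / (m - 1)
  lapply(centers, function(cc) {
    switch(family,
      trimf = mf_tri(cc - h, cc, cc + h),
      gaussmf = mf_gauss(h / (2 * sqrt(2 * log(2))), cc),
      gbellmf = mf_gbell(h / 2, 2, cc),
      pimf = mf_pi(cc - 0.9 * h, cc - 0.1 * h, cc + 0.1 * h, cc + 0.9 * h),
      stop("unknown membership family: ", family)
    )
  })
}

#' Fuzzy input factor
#'
#' One crisp input of an ANFIS model: a named factor with its observed domain
#' and an ordered list of membership functions created by uniform grid
#' partition (centers equally spaced, adjacent curves crossing near degree
#' 0.5).
#'
#' @param name Factor label.
#' @param domain Length-2 numeric range the membership grid spans.
#' @param n_mf Number of membership functions (>= 2).
#' @param family Membership family: `"trimf"`, `"gaussmf"`, `"gbellmf"` or
#'   `"pimf"`.
#' @return A `fuzzy_input` object.
#' @export
fuzzy_input <- function(name, domain, n_mf = 3,
                        family = c("gbellmf", "trimf", "gaussmf", "pimf")) {
  family <- match.arg(family)
  stopifnot(length(domain) == 2, is.finite(domain), n_mf >= 2)
  if (domain[2] <= domain[1]) {
    stop("degenerate input domain for '", name, "': constant factor",
         call. = FALSE)
  }
  structure(list(name = name, domain_min = domain[1], domain_max = domain[2],
                 mfs = grid_partition_mfs(family, n_mf, domain[1], domain[2]),
                 family = family),
            class = "fuzzy_input")
}
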