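# Universal gas constant, J/(mol K)
GAS_CONSTANT <- 8.314

#' Moisture content on a dry basis
#'
#' Computes the dry-basis moisture content (percent) of a sample from its wet
#' and dry weights: \eqn{M_c = 100 (W_w - D_w) / D_w}.
#'
#' @param wet_weight_g Sample wet weight, grams.
#' @param dry_weight_g Sample bone-dry weight, grams; must be positive.
#' @return Moisture content in percent, dry basis. Vectorised.
#' @examples
#' moisture_content(2, 1)   # 100% d.b.
#' @export
moisture_content <- function(wet_weight_g, dry_weight_g) {
  if (any(!is.finite(dry_weight_g)) || any(dry_weight_g <= 0)) {
    stop("dry_weight_g must be positive and finite", call. = FALSE)
  }
  100 * (wet_weight_g - dry_weight_g) / dry_weight_g
}

#' Moisture ratio
#'
#' Dimensionless moisture ratio \eqn{MR = (M_t - M_e) / (M_o - M_e)}, equal to
#' 1 at the start of drying and decaying towards 0 as the sample approaches
#' its equilibrium moisture content.
#'
#' @param Mt Moisture content at time t (g water / g dry matter).
#' @param Mo Initial moisture content; must exceed `Me`.
#' @param Me Equilibrium moisture content. Defaults to 0, the standard
#'   thin-layer simplification when the equilibrium value is not measured.
#' @return Moisture ratio, dimensionless. Vectorised over `Mt`.
#' @export
moisture_ratio <- function(Mt, Mo, Me = 0) {
  if (!is.finite(Mo) || !is.finite(Me) || Mo <= Me) {
    stop("degenerate curve: Mo must exceed Me", call. = FALSE)
  }
  (Mt - Me) / (Mo - Me)
}

#' Drying curve for one pretreatment x temperature cell
#'
#' Bundles the ordered (time, moisture ratio) series of a single drying run
#' with its geometry metadata. Times must be strictly increasing from 0 and
#' the first moisture ratio must equal 1 (within `tol`); values outside
#' [-tol, 1 + tol] are flagged with a warning but retained.
#'
#' @param times Elapsed drying time, minutes, strictly increasing from 0.
#' @param moisture_ratios Moisture ratio at each time.
#' @param pretreatment_min Minutes of 60 C warm-water blanching (0 = none).
#' @param temperature_C Dryer air temperature, degrees Celsius.
#' @param radius_m Characteristic (sphere) radius of the fruit, metres.
#' @param initial_mass_kg Initial sample mass W0, kg.
#' @param tol Tolerance for the MR range checks.
#' @return An object of class `drying_curve`.
#' @export
drying_curve <- function(times, moisture_ratios, pretreatment_min = 0,
                         temperature_C = 60, radius_m = 0.02,
                         initial_mass_kg = 0.2, tol = 0.05) {
  stopifnot(length(times) == length(moisture_ratios), length(times) >= 1)
  if (!is.finite(radius_m) || radius_m <= 0) {
    stop("radius_m must be positive", call. = FALSE)
  }
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing from 0", call. = FALSE)
  }
  if (abs(moisture_ratios[1] - 1) > tol) {
    stop("first moisture ratio must equal 1 (within tol)", call. = FALSE)
  }
  out_of_range <- moisture_ratios < -tol | moisture_ratios > 1 + tol
  if (any(out_of_range)) {
    warning(sprintf("%d moisture ratio value(s) outside [0, 1] by more than tol",
                    sum(out_of_range)), call. = FALSE)
  }
  structure(
    list(times = as.numeric(times),
         moisture_ratios = as.numeric(moisture_ratios),
         pretreatment_min = pretreatment_min,
         temperature_C = temperature_C,
         radius_m = radius_m,
         initial_mass_kg = initial_mass_kg),
    class = "drying_curve")
}

#' @export
print.drying_curve <- function(x, ...) {
  cat(sprintf("Drying curve: %g min blanch, %g C, %d points, t in [0, %g] min\n",
              x$pretreatment_min, x$temperature_C, length(x$times),
              max(x$times)))
  invisible(x)
}

#' Fit ln(MR) against time
#'
#' Ordinary least-squares regression of log moisture ratio on drying time over
#' the points with MR above `min_mr`. Under the one-term Fick sphere solution
#' the late-time plot of ln MR versus t is a straight line whose slope is
#' \eqn{-\pi^2 D_{eff} / r^2}.
#'
#' @param curve A [drying_curve()].
#' @param min_mr Smallest moisture ratio admitted to the regression; points at
#'   or below it (including any non-positive MR, whose log is undefined) are
#'   excluded with a message.
#' @param max_mr Largest moisture ratio admitted. The default `Inf` keeps
#'   every point; a bound near 0.2 restricts the regression to the late-time
#'   regime where the one-term sphere solution dominates (the n = 2 series
#'   term contributes under ~3% there), which is the appropriate window when
#'   recovering a diffusivity from a full multi-term curve.
#' @return A `linear_fit` list: `slope`, `intercept`, `r_squared`, `n_points`.
#' @export
fit_ln_mr <- function(curve, min_mr = 0.01, max_mr = Inf) {
  stopifnot(inherits(curve, "drying_curve"))
  keep <- is.finite(curve$moisture_ratios) & curve$moisture_ratios > min_mr &
    curve$moisture_ratios <= max_mr
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("fit_ln_mr: excluding %d point(s) with MR <= %g",
                    n_dropped, min_mr))
  }
  if (sum(keep) < 2) {
    stop("insufficient data: fewer than 2 points with MR > min_mr",
         call. = FALSE)
  }
  t <- curve$times[keep]
  y <- log(curve$moisture_ratios[keep])
  fit <- stats::lm.fit(cbind(1, t), y)
  res <- fit$residuals
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = r2, n_points = length(t)),
            class = "linear_fit")
}

#' Effective moisture diffusivity from the regression slope
#'
#' Converts the slope of the ln MR versus t regression into an effective
#' moisture diffusivity via \eqn{K_L = D_{eff} \pi^2 / r^2}.
#'
#' Two unit conventions are supported. `mode = "table"` applies
#' \eqn{D_{eff} = |K_L| r^2 / \pi^2} to the slope exactly as given, which
#' reproduces published diffusivity tables computed from slopes against time
#' in seconds. `mode = "si"` additionally divides by 60 so that a slope fitted
#' against time in minutes (as [fit_ln_mr()] produces on minute-based curves)
#' yields a diffusivity in m^2/s.
#'
#' @param fit A `linear_fit` from [fit_ln_mr()], or a bare numeric slope.
#' @param radius_m Characteristic sphere radius, metres.
#' @param mode `"table"` (slope used as-is) or `"si"` (per-minute slope
#'   converted to per-second).
#' @return A `diffusivity_result` list: `deff`, `fit`, `mode`, `physical`.
#'   A non-negative slope yields `deff = 0` flagged `physical = FALSE` with a
#'   warning.
#' @export
deff_from_slope <- function(fit, radius_m = 0.02, mode = c("table", "si")) {
  mode <- match.arg(mode)
  if (is.numeric(fit)) {
    fit <- structure(list(slope = fit, intercept = NA_real_,
                          r_squared = NA_real_, n_points = NA_integer_),
                     class = "linear_fit")
  }
  stopifnot(inherits(fit, "linear_fit"), radius_m > 0)
  if (fit$slope >= 0 && fit$slope != 0) {
    warning("non-negative ln-MR slope: diffusivity is non-physical, returning 0",
            call. = FALSE)
  }
  deff <- if (fit$slope < 0) abs(fit$slope) * radius_m^2 / pi^2 else 0
  if (mode == "si") deff <- deff / 60
  structure(list(deff = deff, fit = fit, mode = mode,
                 physical = fit$slope < 0),
            class = "diffusivity_result")
}

#' Arrhenius fit of diffusivity against temperature
#'
#' Regresses \eqn{\ln D_{eff}} on inverse absolute temperature and reports the
#' activation energy \eqn{E_a = -slope \times R} (kJ/mol) and pre-exponential
#' factor \eqn{D_0 = \exp(intercept)}. The activation energy is invariant to
#' any constant rescaling of the diffusivity units.
#'
#' @param deff_by_temp Named numeric vector: names are temperatures in Celsius,
#'   values are positive diffusivities. Duplicated temperatures are averaged
#'   with a warning.
#' @return An `arrhenius_result` list: `ea_kj_per_mol`, `d0`, `fit`
#'   (a `linear_fit` of ln Deff on 1/T).
#' @export
arrhenius_fit <- function(deff_by_temp) {
  if (is.null(names(deff_by_temp))) {
    stop("deff_by_temp must be named by temperature in Celsius", call. = FALSE)
  }
  temps <- as.numeric(names(deff_by_temp))
  deff <- as.numeric(deff_by_temp)
  if (any(!is.finite(deff)) || any(deff <= 0)) {
    stop("all diffusivities must be positive", call. = FALSE)
  }
  if (anyDuplicated(temps)) {
    warning("duplicate temperatures averaged", call. = FALSE)
    deff <- tapply(deff, temps, mean)
    temps <- as.numeric(names(deff))
    deff <- as.numeric(deff)
  }
  if (length(unique(temps)) < 2) {
    stop("need at least 2 distinct temperatures", call. = FALSE)
  }
  inv_T <- 1 / (temps + 273.15)
  y <- log(deff)
  fit <- stats::lm.fit(cbind(1, inv_T), y)
  res <- fit$residuals
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  lf <- structure(list(slope = unname(fit$coefficients[2]),
                       intercept = unname(fit$coefficients[1]),
                       r_squared = r2, n_points = length(y)),
                  class = "linear_fit")
  structure(list(ea_kj_per_mol = -lf$slope * GAS_CONSTANT / 1000,
                 d0 = exp(lf$intercept), fit = lf),
            class = "arrhenius_result")
}

#' Total energy consumed by a convective drying run
#'
#' \eqn{E_t = A v \rho_a c_a \Delta T D_t}: the drying air mass flow
#' (A v rho_a, kg/s) times its sensible heat (c_a Delta T, kJ/kg) is the
#' heater power in kW; multiplied by the drying time in hours it gives kWh
#' directly.
#'
#' @param area_m2 Tray area A, m^2.
#' @param velocity_m_s Drying air velocity v, m/s.
#' @param rho_air Air density, kg/m^3.
#' @param c_air Air specific heat, kJ/(kg C).
#' @param delta_T Temperature rise of the drying air, C.
#' @param drying_time_h Drying time, hours.
#' @return Total energy, kWh.
#' @export
total_energy <- function(area_m2, velocity_m_s, rho_air, c_air, delta_T,
                         drying_time_h) {
  args <- c(area_m2, velocity_m_s, rho_air, c_air, delta_T, drying_time_h)
  if (any(!is.finite(args)) || any(args < 0)) {
    stop("all energy inputs must be non-negative and finite", call. = FALSE)
  }
  area_m2 * velocity_m_s * rho_air * c_air * delta_T * drying_time_h
}

#' Specific energy consumption
#'
#' \eqn{E_s = E_t / W_0}: total drying energy per kilogram of fresh sample.
#'
#' @param et_kwh Total energy, kWh.
#' @param initial_mass_kg Initial sample mass W0, kg; must be positive.
#' @return Specific energy, kWh/kg.
#' @export
specific_energy <- function(et_kwh, initial_mass_kg) {
  if (!is.finite(initial_mass_kg) || initial_mass_kg <= 0) {
    stop("initial_mass_kg must be positive", call. = FALSE)
  }
  et_kwh / initial_mass_kg
}

#' Slope-method kinetics over a long-format drying dataset
#'
#' Runs the full slope-method pipeline on a long-format drying dataset: per
#' pretreatment x temperature cell, fits ln MR against time and converts the
#' slope to an effective moisture diffusivity; then, per pretreatment, fits
#' the Arrhenius relation across temperatures.
#'
#' @param data Data frame with columns `pretreatment_min`, `temperature_C`,
#'   `time_min`, `moisture_ratio` (see [read_drying_csv()]).
#' @param radius_m Characteristic radius, metres.
#' @param mode Unit convention passed to [deff_from_slope()].
#' @param min_mr,max_mr Regression window passed to [fit_ln_mr()].
#' @return A list with `diffusivity` (one row per cell: `pretreatment_min`,
#'   `temperature_C`, `deff`, `slope`, `intercept`, `r_squared`, `n_points`)
#'   and `arrhenius` (one row per pretreatment: `pretreatment_min`,
#'   `ea_kj_per_mol`, `d0`, `r_squared`).
#' @export
kinetics_report <- function(data, radius_m = 0.02, mode = c("table", "si"),
                            min_mr = 0.01, max_mr = Inf) {
  mode <- match.arg(mode)
  data <- validate_drying_data(data)
  cells <- unique(data[, c("pretreatment_min", "temperature_C")])
  cells <- cells[order(cells$pretreatment_min, cells$temperature_C), ,
                 drop = FALSE]
  diff_rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- data[data$pretreatment_min == cells$pretreatment_min[i] &
                  data$temperature_C == cells$temperature_C[i], ]
    sub <- sub[order(sub$time_min), ]
    cur <- drying_curve(sub$time_min, sub$moisture_ratio,
                        pretreatment_min = cells$pretreatment_min[i],
                        temperature_C = cells$temperature_C[i],
                        radius_m = radius_m)
    fit <- fit_ln_mr(cur, min_mr = min_mr, max_mr = max_mr)
    dres <- deff_from_slope(fit, radius_m = radius_m, mode = mode)
    data.frame(pretreatment_min = cells$pretreatment_min[i],
               temperature_C = cells$temperature_C[i],
               deff = dres$deff, slope = fit$slope,
               intercept = fit$intercept, r_squared = fit$r_squared,
               n_points = fit$n_points)
  })
  diffusivity <- do.call(rbind, diff_rows)
  arr_rows <- lapply(split(diffusivity, diffusivity$pretreatment_min),
                     function(d) {
    if (nrow(d) < 2 || any(d$deff <= 0)) return(NULL)
    a <- arrhenius_fit(stats::setNames(d$deff, d$temperature_C))
    data.frame(pretreatment_min = d$pretreatment_min[1],
               ea_kj_per_mol = a$ea_kj_per_mol, d0 = a$d0,
               r_squared = a$fit$r_squared)
  })
  arrhenius <- do.call(rbind, Filter(Negate(is.null), arr_rows))
  rownames(arrhenius) <- NULL
  list(diffusivity = diffusivity, arrhenius = arrhenius)
}
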