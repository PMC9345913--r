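#' Published slope-method diffusivities for blanched miracle berry fruit
#'
#' Reference values from the source drying study: per pretreatment (minutes of
#' 60 C warm-water blanch, 0 = unblanched) and drying temperature, the
#' reported effective moisture diffusivity (m^2/s), the slope and intercept of
#' the ln MR regression, and its R^2. These parameterize the synthetic
#' generator and serve as desk-check inputs; two of the twelve rows
#' (pretreatments 0 and 10 at 50 C) are known to be ~5-6% inconsistent with
#' their own printed slopes, likely from slope rounding.
#'
#' @return Data frame with columns `pretreatment_min`, `temperature_C`,
#'   `deff`, `slope`, `intercept`, `r_squared`, `slope_consistent`.
#' @export
reference_diffusivities <- function() {
  d <- data.frame(
    pretreatment_min = rep(c(0, 10, 5, 3), each = 3),
    temperature_C = rep(c(50, 60, 70), times = 4),
    deff = c(5.1052e-9, 8.3061e-9, 9.5217e-9,
             5.2268e-9, 8.5898e-9, 1.1628e-8,
             7.8199e-9, 1.01e-8, 1.7706e-8,
             1.1507e-8, 1.3249e-8, 2.5607e-8),
    slope = c(-0.000134, -0.000205, -0.000235,
              -0.000136, -0.000212, -0.000287,
              -0.000193, -0.000249, -0.000437,
              -0.000284, -0.000327, -0.000632),
    intercept = c(0.170462, 0.162015, 0.086470,
                  0.033734, 0.136115, 0.086887,
                  0.128717, 0.075713, 0.177591,
                  0.275632, 0.160177, 0.234027),
    r_squared = c(0.9600, 0.9895, 0.9685,
                  0.9553, 0.9670, 0.9766,
                  0.9602, 0.9863, 0.9808,
                  0.9540, 0.9704, 0.9821))
  d$slope_consistent <- abs(abs(d$slope) * 0.02^2 / pi^2 - d$deff) / d$deff <
    0.001
  d
}

#' Published activation energies per pretreatment
#'
#' @return Data frame with columns `pretreatment_min`, `ea_kj_per_mol`.
#' @export
reference_activation_energies <- function() {
  data.frame(pretreatment_min = c(0, 10, 5, 3),
             ea_kj_per_mol = c(28.8589, 36.9071, 37.4808, 36.5912))
}

#' Fick sphere moisture-ratio series
#'
#' Analytical solution of Fick's second law for a sphere with uniform initial
#' moisture and constant surface condition:
#' \deqn{MR(t) = \frac{6}{\pi^2} \sum_{n=1}^{N} \frac{1}{n^2}
#'   \exp\left(-\frac{n^2 \pi^2 D_{eff} t}{r^2}\right)}
#' The series starts at n = 1; at t = 0 and N to infinity it sums to 1 by the
#' Basel identity, and at long times the n = 1 term dominates.
#'
#' @param deff Effective moisture diffusivity, m^2/s.
#' @param r Sphere radius, metres.
#' @param t_s Time in seconds (vectorised).
#' @param n_terms Number of series terms (>= 1).
#' @return Moisture ratio values in (0, 1], decreasing in `t_s`.
#' @export
mr_series <- function(deff, r, t_s, n_terms = 50) {
  stopifnot(deff > 0, r > 0, all(t_s >= 0), n_terms >= 1)
  n <- seq_len(n_terms)
  # outer over terms; t_s vectorised
  terms <- outer(t_s, n, function(tt, nn) {
    exp(-nn^2 * pi^2 * deff * tt / r^2) / nn^2
  })
  as.numeric(6 / pi^2 * rowSums(terms))
}

#' Synthetic drying-dataset generator configuration
#'
#' Encodes the source study's design: 4 warm-water blanching pretreatments
#' (0, 3, 5, 10 min at 60 C) crossed with 3 drying temperatures (50/60/70 C),
#' sample weights recorded every 10 min for the first two hours and every
#' 30 min thereafter until the sample is effectively dry. Per-pretreatment
#' Arrhenius parameters (Ea, D0) default to the values obtained by regressing
#' the published diffusivity table, so generated curves reproduce the study's
#' drying-time ordering (higher temperature and shorter blanch dry faster)
#' and its overall record count (about 255 at defaults).
#'
#' @param pretreatments Blanching times, minutes.
#' @param temperatures Drying temperatures, Celsius.
#' @param ea_by_pretreatment Named vector (names = pretreatment minutes) of
#'   activation energies, kJ/mol.
#' @param d0_by_pretreatment Named vector of Arrhenius pre-exponential
#'   factors, m^2/s.
#' @param radius_m Characteristic sphere radius, metres.
#' @param initial_mass_kg Initial tray load W0, kg.
#' @param fine_interval_min,fine_until_min,coarse_interval_min Weighing
#'   schedule: every `fine_interval_min` minutes up to `fine_until_min`,
#'   every `coarse_interval_min` minutes after.
#' @param stop_mr Generation stops once MR falls below this.
#' @param noise_sd Multiplicative Gaussian noise sd on MR (weighing error
#'   scales with mass); 0 disables noise.
#' @param n_series_terms Series truncation for [mr_series()].
#' @param seed Integer seed for the noise.
#' @return A `generator_config` list.
#' @export
generator_config <- function(pretreatments = c(0, 3, 5, 10),
                             temperatures = c(50, 60, 70),
                             ea_by_pretreatment = NULL,
                             d0_by_pretreatment = NULL,
                             radius_m = 0.02,
                             initial_mass_kg = 0.2,
                             fine_interval_min = 10,
                             fine_until_min = 120,
                             coarse_interval_min = 30,
                             stop_mr = 0.01,
                             noise_sd = 0.01,
                             n_series_terms = 50,
                             seed = 1) {
  if (is.null(ea_by_pretreatment) || is.null(d0_by_pretreatment)) {
    ref <- reference_diffusivities()
    fits <- lapply(split(ref, ref$pretreatment_min), function(d) {
      arrhenius_fit(stats::setNames(d$deff, d$temperature_C))
    })
    if (is.null(ea_by_pretreatment)) {
      ea_by_pretreatment <- vapply(fits, `[[`, numeric(1), "ea_kj_per_mol")
    }
    if (is.null(d0_by_pretreatment)) {
      d0_by_pretreatment <- vapply(fits, `[[`, numeric(1), "d0")
    }
  }
  need <- as.character(pretreatments)
  if (!all(need %in% names(ea_by_pretreatment)) ||
      !all(need %in% names(d0_by_pretreatment))) {
    stop("ea/d0_by_pretreatment must be named by every pretreatment",
         call. = FALSE)
  }
  stopifnot(radius_m > 0, initial_mass_kg > 0, stop_mr > 0, stop_mr < 1,
            noise_sd >= 0, n_series_terms >= 1,
            fine_interval_min > 0, coarse_interval_min > 0)
  structure(list(pretreatments = pretreatments, temperatures = temperatures,
                 ea_by_pretreatment = ea_by_pretreatment,
                 d0_by_pretreatment = d0_by_pretreatment,
                 radius_m = radius_m, initial_mass_kg = initial_mass_kg,
                 fine_interval_min = fine_interval_min,
                 fine_until_min = fine_until_min,
                 coarse_interval_min = coarse_interval_min,
                 stop_mr = stop_mr, noise_sd = noise_sd,
                 n_series_terms = n_series_terms, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic drying dataset
#'
#' For each pretreatment x temperature cell, draws the effective moisture
#' diffusivity from the Arrhenius law \eqn{D_{eff} = D_0 \exp(-E_a / RT)} and
#' samples the Fick sphere moisture ratio on the weighing schedule until MR
#' drops below `stop_mr`. Optional multiplicative Gaussian noise
#' \eqn{MR (1 + \epsilon)} is clipped to \[0, 1\]; the t = 0 point is pinned
#' at MR = 1 (the normalization point of a real experiment).
#'
#' @param config A [generator_config()].
#' @return List with `data` (long-format data frame: `sample_id`,
#'   `pretreatment_min`, `temperature_C`, `time_min`, `moisture_ratio`) and
#'   `ground_truth` (per cell: true `deff` m^2/s and `ea_kj_per_mol`).
#' @export
generate_drying_data <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  set.seed(config$seed)
  on.exit(.Random.seed_restore(old))
  rows <- list(); truth <- list()
  for (p in config$pretreatments) {
    ea <- config$ea_by_pretreatment[[as.character(p)]]
    d0 <- config$d0_by_pretreatment[[as.character(p)]]
    for (temp in config$temperatures) {
      deff <- d0 * exp(-ea * 1000 / (GAS_CONSTANT * (temp + 273.15)))
      # time (min) at which the one-term solution hits stop_mr: schedule bound
      t_stop <- (log(6 / pi^2) - log(config$stop_mr)) * config$radius_m^2 /
        (pi^2 * deff) / 60
      fine <- seq(0, config$fine_until_min, by = config$fine_interval_min)
      coarse <- seq(config$fine_until_min + config$coarse_interval_min,
                    max(t_stop + config$coarse_interval_min,
                        config$fine_until_min + config$coarse_interval_min),
                    by = config$coarse_interval_min)
      times <- c(fine, coarse)
      mr <- mr_series(deff, config$radius_m, times * 60,
                      n_terms = config$n_series_terms)
      keep <- mr >= config$stop_mr
      times <- times[keep]; mr <- mr[keep]
      if (config$noise_sd > 0) {
        mr <- mr * (1 + stats::rnorm(length(mr), 0, config$noise_sd))
        mr <- pmin(pmax(mr, 0), 1)
        mr[1] <- 1   # t = 0 is the normalization point
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("p%02d_T%d", p, temp),
        pretreatment_min = p, temperature_C = temp,
        time_min = times, moisture_ratio = mr)
      truth[[length(truth) + 1L]] <- data.frame(
        pretreatment_min = p, temperature_C = temp,
        deff_true = deff, ea_true = ea, d0_true = d0)
    }
  }
  list(data = do.call(rbind, c(rows, make.row.names = FALSE)),
       ground_truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}
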