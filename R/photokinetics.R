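# Closed-form photolysis kinetics for the four candidate reaction schemes.
#
# Scheme (model II, the general case):
#   A --k1[hv]--> B --k2'[hv]--> C --> products (D via oxidation etc.)
#   A --k3[hv]--> C
# Model I:  k3 = 0.  Model III: the B->C step is spontaneous (k2' = k2/[hv],
# so its first-order rate k2'[hv] = k2 is light-independent).  Model IV:
# k2 = 0 (no B->C step).  C is consumed effectively instantaneously, so it
# is reported as consumed A not yet present as A, B or D-precursor.

#' Photolysis kinetic parameters
#'
#' Per-photon rate coefficients of the diazirine photolysis scheme. The
#' first-order rates are these coefficients multiplied by the optical power
#' density `[hv]` (mW/cm^2), so the coefficients carry units cm^2/(mW s).
#'
#' @param k1 A -> B (diazo) rate coefficient, cm^2/(mW s).
#' @param k2 B -> C (carbene) rate coefficient, cm^2/(mW s). For model III
#'   this is interpreted as a light-independent first-order rate (s^-1).
#' @param k3 direct A -> C rate coefficient, cm^2/(mW s).
#' @param A0 initial diazirine concentration (normalized signal; default 1).
#' @param phi_D product-yield factor in `[0, 1]`: the fraction of consumed C
#'   routed to the monitored product D (the ratio k_ox/(k_ox + k_others);
#'   the individual rates are unidentifiable, only the ratio is kept).
#' @return An object of class `photolysis_params`.
#' @examples
#' photolysis_params(k1 = 2.13e-4, k2 = 0.73e-4, k3 = 0.19e-4)
#' @export
photolysis_params <- function(k1, k2, k3 = 0, A0 = 1, phi_D = 1) {
  stopifnot(is.numeric(k1), is.numeric(k2), is.numeric(k3),
            is.numeric(A0), is.numeric(phi_D))
  if (k1 < 0 || k2 < 0 || k3 < 0)
    abort("rate coefficients k1, k2, k3 must be >= 0", class = "photoxl_validation")
  if (A0 <= 0)
    abort("A0 must be > 0", class = "photoxl_validation")
  if (phi_D < 0 || phi_D > 1)
    abort("phi_D must lie in [0, 1]", class = "photoxl_validation")
  structure(list(k1 = k1, k2 = k2, k3 = k3, A0 = A0, phi_D = phi_D),
            class = "photolysis_params")
}

#' @export
print.photolysis_params <- function(x, ...) {
  cat("Photolysis parameters (per-photon coefficients, cm^2/(mW s)):\n")
  cat(sprintf("  k1 = %g, k2 = %g, k3 = %g;  A0 = %g, phi_D = %g\n",
              x$k1, x$k2, x$k3, x$A0, x$phi_D))
  invisible(x)
}

#' Irradiation condition
#'
#' @param power_density optical power density `[hv]`, mW/cm^2.
#' @param time irradiation duration, s.
#' @return An object of class `irradiation_condition`.
#' @export
irradiation_condition <- function(power_density, time = 0) {
  if (any(power_density < 0) || any(time < 0))
    abort("power_density and time must be >= 0", class = "photoxl_validation")
  structure(list(power_density = power_density, time = time),
            class = "irradiation_condition")
}

model_ids <- c("I", "II", "III", "IV")

check_model_params <- function(model, params) {
  model <- match.arg(model, model_ids)
  if (model == "I" && params$k3 != 0)
    abort("model I requires k3 = 0", class = "photoxl_validation")
  if (model == "IV" && params$k2 != 0)
    abort("model IV requires k2 = 0", class = "photoxl_validation")
  model
}

# Effective per-photon B->C coefficient k2' for a given model and power:
# k2' = k2 except model III where k2' = k2/[hv] (so k2'[hv] = k2, a
# light-independent spontaneous isomerization).
effective_k2 <- function(model, k2, power_density) {
  if (model == "III") {
    if (power_density <= 0)
      abort("model III requires power_density > 0", class = "photoxl_validation")
    k2 / power_density
  } else {
    k2
  }
}

# Relative tolerance below which the degenerate closed-form branch
# (k1 - k2' + k3 -> 0) is taken.
.deg_tol <- 1e-9

#' Closed-form species time courses
#'
#' Evaluates the closed-form concentrations of diazirine A, diazo
#' intermediate B, product D, and cumulative carbene throughput C on a time
#' grid, for one of the four kinetic models. With `lamA = (k1+k3)[hv]` and
#' `lamB = k2'[hv]`:
#' \deqn{A(t) = A_0 e^{-\lambda_A t}}
#' \deqn{B(t) = \frac{k_1 A_0}{k_1 - k_2' + k_3}(e^{-\lambda_B t} - e^{-\lambda_A t})}
#' \deqn{D(t) = \phi_D A_0\left(1 - \frac{k_1}{k_1-k_2'+k_3} e^{-\lambda_B t}
#'   + \frac{k_2'-k_3}{k_1-k_2'+k_3} e^{-\lambda_A t}\right)}
#' When the denominator `k1 - k2' + k3` degenerates the analytic limit
#' `B(t) = k1 [hv] A0 t exp(-lamA t)` is used and D is obtained from the
#' conservation identity `D = phi_D (A0 - A - B)`, which the closed forms
#' satisfy exactly. C is reported as cumulative consumed A not retained in
#' A or B (`A0 - A - B`), since carbene is consumed effectively instantly.
#'
#' @param model one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param params a [photolysis_params()].
#' @param condition an [irradiation_condition()] (its `power_density` is
#'   used), or a single power density in mW/cm^2.
#' @param time_grid nonnegative, nondecreasing times, s.
#' @return A tibble with columns `time_s`, `species` (`"A"`, `"B"`, `"D"`,
#'   `"C"`), `value`, `power_mw_cm2`.
#' @examples
#' p <- photolysis_params(k1 = 2.13e-4, k2 = 0.73e-4, k3 = 0.19e-4)
#' species_timecourse("II", p, 242, time_grid = seq(0, 120, 5))
#' @export
species_timecourse <- function(model, params, condition, time_grid) {
  model <- check_model_params(model, params)
  stopifnot(inherits(params, "photolysis_params"))
  power <- if (inherits(condition, "irradiation_condition"))
    condition$power_density else condition
  if (length(power) != 1 || power < 0)
    abort("condition must carry a single power density >= 0",
          class = "photoxl_validation")
  if (any(time_grid < 0) || is.unsorted(time_grid))
    abort("time_grid must be nonnegative and sorted", class = "photoxl_validation")

  sp <- timecourse_values(model, params, power, time_grid)
  tibble(
    time_s = rep(time_grid, 4L),
    species = rep(c("A", "B", "D", "C"), each = length(time_grid)),
    value = c(sp$A, sp$B, sp$D, sp$C),
    power_mw_cm2 = power
  )
}

# Internal: closed-form values as a list of numeric vectors.
timecourse_values <- function(model, params, power, t) {
  k1 <- params$k1; k3 <- params$k3; A0 <- params$A0; phi <- params$phi_D
  k2p <- effective_k2(model, params$k2, power)
  lamA <- (k1 + k3) * power
  lamB <- k2p * power
  A <- A0 * exp(-lamA * t)
  delta <- k1 - k2p + k3
  if (abs(delta) < .deg_tol * (k1 + k2p + k3)) {
    B <- k1 * power * A0 * t * exp(-lamA * t)
    D <- phi * (A0 - A - B)
  } else {
    B <- k1 * A0 / delta * (exp(-lamB * t) - exp(-lamA * t))
    D <- phi * A0 * (1 - k1 / delta * exp(-lamB * t) +
                       (k2p - k3) / delta * exp(-lamA * t))
  }
  list(A = A, B = B, D = D, C = A0 - A - B)
}

#' Molar photon delivery rate of a uniform irradiation field
#'
#' Converts an optical power density into the rate at which photons are
#' delivered per unit solution volume, assuming no attenuation through the
#' sample (the photon density well exceeds the chromophore concentration).
#' `flux = P / (E_photon N_A V)` with `E_photon = hc/lambda` and `V` the
#' illuminated volume per cm^2 of cross-section.
#'
#' @param power_density mW/cm^2.
#' @param wavelength_nm wavelength, nm (default 365).
#' @param path_length_cm optical path length, cm (default 1).
#' @return photon delivery rate, uM/s.
#' @examples
#' photon_flux(10)   # ~30 uM/s at 10 mW/cm^2, 365 nm, 1 cm path
#' @export
photon_flux <- function(power_density, wavelength_nm = 365, path_length_cm = 1) {
  if (any(power_density < 0))
    abort("power_density must be >= 0", class = "photoxl_validation")
  if (wavelength_nm <= 0 || path_length_cm <= 0)
    abort("wavelength and path length must be > 0", class = "photoxl_validation")
  h <- 6.62607015e-34      # J s
  c0 <- 2.99792458e8       # m/s
  NA_ <- 6.02214076e23     # 1/mol
  e_photon <- h * c0 / (wavelength_nm * 1e-9)              # J
  photons_s_cm2 <- power_density * 1e-3 / e_photon         # photons/(s cm^2)
  mol_s <- photons_s_cm2 / NA_                             # mol/(s cm^2)
  vol_l <- path_length_cm * 1e-3                           # L per cm^2 section
  mol_s / vol_l * 1e6                                      # uM/s
}

#' Flow-cell geometry of the photo-reactor
#'
#' @param inner_diameter_mm tube inner diameter, mm.
#' @param tube_length_m illuminated tube length, m.
#' @param flow_rate_ml_min volumetric flow rate, mL/min.
#' @param duty_cycle PWM duty cycle in `[0, 1]`; the LED field is pulsed so
#'   the effective irradiation time is `duty_cycle * residence_time`.
#' @return An object of class `flow_cell_geometry`.
#' @examples
#' g <- flow_cell_geometry(0.5, 1, 0.200)
#' residence_time(g)   # 58.9 s
#' @export
flow_cell_geometry <- function(inner_diameter_mm, tube_length_m,
                               flow_rate_ml_min, duty_cycle = 1) {
  if (inner_diameter_mm <= 0 || tube_length_m <= 0 || flow_rate_ml_min <= 0)
    abort("geometry fields must be > 0", class = "photoxl_validation")
  if (duty_cycle < 0 || duty_cycle > 1)
    abort("duty_cycle must lie in [0, 1]", class = "photoxl_validation")
  structure(list(inner_diameter_mm = inner_diameter_mm,
                 tube_length_m = tube_length_m,
                 flow_rate_ml_min = flow_rate_ml_min,
                 duty_cycle = duty_cycle),
            class = "flow_cell_geometry")
}

#' @rdname flow_cell_geometry
#' @param geometry a [flow_cell_geometry()].
#' @return `tube_volume()`: illuminated volume, mL.
#' @export
tube_volume <- function(geometry) {
  stopifnot(inherits(geometry, "flow_cell_geometry"))
  r_cm <- geometry$inner_diameter_mm / 2 / 10
  len_cm <- geometry$tube_length_m * 100
  pi * r_cm^2 * len_cm
}

#' @rdname flow_cell_geometry
#' @return `residence_time()`: residence time of the sample in the
#'   illuminated tube, s.
#' @export
residence_time <- function(geometry) {
  tube_volume(geometry) / geometry$flow_rate_ml_min * 60
}

#' @rdname flow_cell_geometry
#' @return `pwm_irradiation_time()`: effective irradiation time under the
#'   pulse-width-modulation scheme, `duty_cycle * residence_time`, s.
#' @export
pwm_irradiation_time <- function(geometry) {
  geometry$duty_cycle * residence_time(geometry)
}
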