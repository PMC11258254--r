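# Shared fixtures and independent oracles.

# Per-photon coefficients recovered by the kinetic analysis: slope of the
# composite decay rate 2.32e-4 cm^2/(mW s), k2 0.73e-4 cm^2/(mW s),
# branching ratio 0.92 at low power.
reference_kin <- function(ratio = 0.92) {
  ktot <- 2.32e-4
  photolysis_params(k1 = ratio * ktot, k2 = 0.73e-4,
                    k3 = (1 - ratio) * ktot)
}

# Numerical ODE oracle for the A/B/D system, independent of the closed
# forms: dA/dt = -(k1+k3)[hv] A; dB/dt = k1[hv] A - k2'[hv] B;
# dD/dt = phi (k3[hv] A + k2'[hv] B).
ode_timecourse <- function(model, params, power, time_grid) {
  k2p <- if (model == "III") params$k2 / power else params$k2
  k1 <- params$k1; k3 <- params$k3; phi <- params$phi_D
  rhs <- function(t, y, p) {
    list(c(A = -(k1 + k3) * power * y[["A"]],
           B = k1 * power * y[["A"]] - k2p * power * y[["B"]],
           D = phi * (k3 * power * y[["A"]] + k2p * power * y[["B"]])))
  }
  out <- deSolve::lsoda(c(A = params$A0, B = 0, D = 0), time_grid, rhs,
                        parms = NULL, rtol = 1e-11, atol = 1e-13)
  as.data.frame(out)
}

# Ideal alpha-helix C-alpha distance by explicit trigonometry.
helix_ca_distance <- function(sep, rise = 1.5, radius = 2.3,
                              twist_deg = 100) {
  th <- sep * twist_deg * pi / 180
  sqrt(2 * radius^2 * (1 - cos(th)) + (sep * rise)^2)
}

# Weighted least squares through the normal equations (no intercept).
wls_slope_oracle <- function(power, rate, w) {
  sum(w * power * rate) / sum(w * power^2)
}

# Standard grid of power levels used in yield-curve tests.
yield_conditions <- function(time_s = 60) {
  data.frame(power_mw_cm2 = c(5, 10, 20, 35, 50, 75, 100, 140, 180, 220,
                              260, 300),
             time_s = time_s)
}
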