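#!/usr/bin/env Rscript

# Step 3: the five-channel reactivity model.
#
# Evaluates the elementary-channel profiles, fits channel weights to
# synthetic yield curves for a diazo-dominant (Ser-like) and a
# carbene-dominant (Ile-like) parameter set, classifies the mechanism,
# maps the adduct-yield surface over irradiation conditions, and
# quantifies water quenching. Writes results/channel_profiles.csv,
# results/weight_fits.csv, results/yield_surface.csv,
# results/water_quench.csv.

suppressMessages(library(photoxl))
suppressMessages(library(dplyr))
dir.create("results", showWarnings = FALSE)

conds <- tibble::tibble(power_mw_cm2 = c(5, 10, 20, 35, 50, 75, 100, 140,
                                         180, 220, 260, 300),
                        time_s = 60)

message("-- Elementary-channel shape functions at t = 60 s --")
pre <- reactivity_preset("diazo-dominant")
prof <- elementary_profiles(pre$kin, pre$ch,
                            irradiation_condition(seq(2, 300, 2), 60),
                            normalize = TRUE)
readr::write_csv(prof, "results/channel_profiles.csv")
peaks <- vapply(c("I_b1", "I_b2", "I_b3", "I_b4"),
                function(cl) prof$power_mw_cm2[which.max(prof[[cl]])], 0)
message(sprintf(
  "  diazo channels peak at %s mW/cm^2; the carbene channel rises monotonically",
  paste(peaks, collapse = ", ")))

message("-- Weight fits on noisy synthetic yield curves (1%% noise) --")
wfits <- bind_rows(lapply(c("diazo-dominant", "carbene-dominant", "mixed"),
                          function(nm) {
  pre <- reactivity_preset(nm)
  cur <- simulate_yield_curves(nm, conds,
                               noise_model(sd = 0.01,
                                           seed = match(nm, c("diazo-dominant",
                                                              "carbene-dominant",
                                                              "mixed"))))
  w <- suppressWarnings(fit_weights(cur, pre$kin, pre$ch))
  cls <- classify_mechanism(w)
  message(sprintf(
    "  %-16s score %+.2f (truth %+.2f) -> %-7s R^2 = %.4f", nm,
    w$mechanism_score, pre$weights$mechanism_score, cls$label, w$goodness))
  tibble(preset = nm, b1 = w$b1, b2 = w$b2, b3 = w$b3, b4 = w$b4,
         c = w$c, mechanism_score = w$mechanism_score,
         label = cls$label, r_squared = w$goodness)
}))
readr::write_csv(wfits, "results/weight_fits.csv")

message("-- Yield surface over (t, [hv]) --")
ys <- yield_surface(pre$kin, pre$ch, t_grid = seq(10, 300, 10),
                    hv_grid = seq(5, 300, 5))
message(sprintf(
  "  diazo-dominant optimum: %d mW/cm^2 at %d s (yield %.2f) -- an interior",
  ys$optimum$power_mw_cm2, ys$optimum$time_s, ys$optimum$yield))
message("  power optimum: harder irradiation converts diazo to carbene first.")
surf <- as.data.frame(as.table(ys$surface))
names(surf) <- c("time_s", "power_mw_cm2", "yield")
readr::write_csv(surf, "results/yield_surface.csv")

message("-- Water quenching --")
wq <- bind_rows(lapply(seq(0, 0.99, length.out = 12), function(w) {
  tibble(water_fraction = w,
         diazo_like = water_quench_yield(pre$weights, pre$ch, w)$yield,
         carbene_like = water_quench_yield(
           reactivity_preset("carbene-dominant")$weights,
           reactivity_preset("carbene-dominant")$ch, w)$yield)
}))
readr::write_csv(wq, "results/water_quench.csv")
message(sprintf(
  "  at 99%% water the Ser-like diazo yield collapses to %.4f of its dry value;",
  wq$diazo_like[nrow(wq)]))
message("  buried (water-shielded) residues are therefore the productive targets.")
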