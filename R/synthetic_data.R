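# Seed-deterministic generators emulating every input the pipeline
# consumes, with ground truth attached so recovery tests are closed-loop.

#' Noise model for synthetic signals
#'
#' @param kind `"multiplicative-gaussian"` (`y (1 + sd * eps)`, the default
#'   for TIC-normalized MRM signals) or `"additive-gaussian"`
#'   (`y + sd * eps`).
#' @param sd noise level (fraction for multiplicative, absolute for
#'   additive); default 0.02, typical of normalized MRM intensities.
#' @param seed integer RNG seed; generation is reproducible given the seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative-gaussian",
                                 "additive-gaussian"),
                        sd = 0.02, seed = 1L) {
  kind <- match.arg(kind)
  if (sd < 0) abort("sd must be >= 0", class = "photoxl_validation")
  structure(list(kind = kind, sd = sd, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(y, noise) {
  if (noise$sd == 0) return(y)
  eps <- rnorm(length(y), 0, noise$sd)
  if (noise$kind == "multiplicative-gaussian") y * (1 + eps) else y + eps
}

#' Simulate MRM traces under a photolysis model
#'
#' Evaluates the closed-form species curves (see [species_timecourse()])
#' at each power density and perturbs them with the noise model. A zero-sd
#' noise model reproduces the closed forms exactly.
#'
#' @param model,params model id and [photolysis_params()].
#' @param powers power densities, mW/cm^2.
#' @param time_grid times, s.
#' @param noise a [noise_model()]; its seed fixes the RNG state.
#' @param replicates replicate traces per power.
#' @param species which species to emit (default A and D, the monitored
#'   ones).
#' @return A tibble with columns `species`, `power_mw_cm2`, `time_s`,
#'   `intensity`, `replicate_id`; ground truth in `attr(, "truth")`.
#' @export
simulate_mrm_traces <- function(model, params, powers, time_grid,
                                noise = noise_model(sd = 0),
                                replicates = 1, species = c("A", "D")) {
  model <- check_model_params(model, params)
  stopifnot(inherits(noise, "noise_model"))
  species <- match.arg(species, c("A", "B", "D"), several.ok = TRUE)
  set.seed(noise$seed)
  rows <- list()
  for (p in powers) {
    sp <- timecourse_values(model, params, p, time_grid)
    for (s in species) {
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- tibble(
          species = s, power_mw_cm2 = p, time_s = time_grid,
          intensity = apply_noise(sp[[s]], noise),
          replicate_id = sprintf("r%d", r))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- list(model = model, params = params, noise = noise)
  out
}

#' Simulate yield-versus-condition curves from a reactivity preset
#'
#' Builds the observed adduct yield as the weighted sum of the five
#' elementary-channel profiles of the preset, then applies the noise
#' model. The generating weights are attached as ground truth.
#'
#' @param preset a preset name for [reactivity_preset()], or a list with
#'   elements `kin`, `ch`, `weights`.
#' @param conditions a tibble with columns `power_mw_cm2`, `time_s`.
#' @param noise a [noise_model()].
#' @param residue residue label carried in the output (e.g. `"S"`).
#' @return A tibble `power_mw_cm2`, `time_s`, `yield`, `residue`;
#'   ground truth (`weights`, `kin`, `ch`) in `attr(, "truth")`.
#' @export
simulate_yield_curves <- function(preset, conditions,
                                  noise = noise_model(sd = 0),
                                  residue = "X") {
  if (is.character(preset)) preset <- reactivity_preset(preset)
  stopifnot(inherits(noise, "noise_model"))
  conditions <- as_tibble(conditions)
  prof <- elementary_profiles(preset$kin, preset$ch,
                              irradiation_condition(conditions$power_mw_cm2,
                                                    conditions$time_s),
                              normalize = TRUE)
  wt <- preset$weights
  y <- wt$b1 * prof$I_b1 + wt$b2 * prof$I_b2 + wt$b3 * prof$I_b3 +
    wt$b4 * prof$I_b4 + wt$c * prof$I_c
  set.seed(noise$seed)
  y <- pmin(pmax(apply_noise(y, noise), 0), 1)
  out <- tibble(power_mw_cm2 = conditions$power_mw_cm2,
                time_s = conditions$time_s, yield = y, residue = residue)
  attr(out, "truth") <- preset
  out
}

#' Generate a toy structure with ideal helical geometry
#'
#' Deterministic coordinate generator standing in for experimental test
#' proteins. `"ideal-helix"` places C-alpha atoms on a standard alpha
#' helix (rise 1.5 A/residue, 100 deg/residue, radius 2.3 A);
#' `"helix-hairpin"` packs two antiparallel such helices side by side
#' (axis separation 9.5 A), burying the facing residues. A pseudo
#' side-chain sphere (CB) is placed radially outward on every non-Gly
#' residue so solvent accessibility is meaningful.
#'
#' @param kind `"ideal-helix"` or `"helix-hairpin"`.
#' @param n_residues number of residues (>= 4).
#' @param sequence one-letter sequence of length `n_residues`; default is
#'   a repeating mixed pattern containing Lys anchors and polar and
#'   non-polar targets.
#' @param protein_id label.
#' @return A [structure_model()] with CA and CB atoms.
#' @export
generate_toy_structure <- function(kind = c("ideal-helix", "helix-hairpin"),
                                   n_residues = 30, sequence = NULL,
                                   protein_id = "toy") {
  kind <- match.arg(kind)
  if (n_residues < 4)
    abort("n_residues must be >= 4", class = "photoxl_validation")
  if (is.null(sequence)) {
    pattern <- strsplit("KAESLIVDGYTKAMELSVIK", "")[[1]]
    sequence <- paste(rep_len(pattern, n_residues), collapse = "")
  }
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) != n_residues)
    abort("sequence length must equal n_residues", class = "photoxl_validation")

  rise <- 1.5; radius <- 2.3; twist <- 100 * pi / 180
  helix_ca <- function(n, offset_x = 0, flip = FALSE) {
    i <- seq_len(n) - 1
    th <- i * twist
    z <- i * rise
    if (flip) z <- max(z) - z
    cbind(x = offset_x + radius * cos(th), y = radius * sin(th), z = z)
  }
  if (kind == "ideal-helix") {
    ca <- helix_ca(n_residues)
    axis_x <- rep(0, n_residues)
  } else {
    n1 <- ceiling(n_residues / 2); n2 <- n_residues - n1
    ca <- rbind(helix_ca(n1, 0), helix_ca(n2, 9.5, flip = TRUE))
    axis_x <- rep(c(0, 9.5), c(n1, n2))
  }
  residues <- tibble(chain = "A", resno = seq_len(n_residues), resid = aa,
                     x = ca[, 1], y = ca[, 2], z = ca[, 3])
  # pseudo side chain: radially outward from the local helix axis
  radial <- cbind(ca[, 1] - axis_x, ca[, 2], 0)
  radial <- radial / sqrt(rowSums(radial^2))
  cb <- ca + 2.4 * radial
  atoms <- dplyr::bind_rows(
    dplyr::mutate(residues, name = "CA", radius = 1.9),
    tibble(chain = "A", resno = seq_len(n_residues), resid = aa,
           name = "CB", x = cb[, 1], y = cb[, 2], z = cb[, 3],
           radius = 2.0)[aa != "G", ])
  structure_model(residues, atoms, protein_id)
}

#' Simulate a cross-link dataset on a structure
#'
#' Draws cross-link records anchored at Lys sites with a controlled polar
#' bias and a controlled fraction of injected over-length contaminants
#' (emulating incorrect assignments, which also carry larger mass
#' errors). Counts are exact by construction: `round(overlength_fraction
#' * n_records)` records are drawn from beyond-limit pairs.
#'
#' @param structure a [structure_model()].
#' @param lys_sites anchor residue numbers (defaults to all Lys in the
#'   structure).
#' @param polar_bias probability that a within-limit target is polar
#'   (Asp/Glu/Tyr/Ser/Thr/His/Arg), in `[0, 1]`.
#' @param overlength_fraction fraction of records drawn from beyond-limit
#'   pairs, in `[0, 1]`.
#' @param n_records number of records.
#' @param seed RNG seed.
#' @param spacer_length,reach_table see [max_allowed_distance()].
#' @param mass_error_sd per-group mass-error sd, ppm, named
#'   `c(good, contaminant)`.
#' @param condition condition label.
#' @return A [crosslink_records()] tibble with ground-truth columns
#'   `truth_overlength`, `truth_polar`.
#' @export
simulate_crosslink_dataset <- function(structure, lys_sites = NULL,
                                       polar_bias = 0.8,
                                       overlength_fraction = 0,
                                       n_records = 100, seed = 1L,
                                       spacer_length = 3.9,
                                       reach_table = default_reach(),
                                       mass_error_sd = c(good = 2,
                                                         contaminant = 5),
                                       condition = "low") {
  if (polar_bias < 0 || polar_bias > 1 ||
      overlength_fraction < 0 || overlength_fraction > 1)
    abort("fractions must lie in [0, 1]", class = "photoxl_validation")
  res <- structure$residues
  if (is.null(lys_sites)) lys_sites <- res$resno[res$resid == "K"]
  if (length(lys_sites) == 0)
    abort("no Lys anchor sites", class = "photoxl_validation")
  if (n_records == 0)
    return(crosslink_records(character(), integer(), integer(),
                             character()))

  # enumerate candidate pairs with distances and limits
  pairs <- expand.grid(site1 = lys_sites, site2 = res$resno)
  pairs <- pairs[pairs$site1 != pairs$site2, ]
  r1t <- res$resid[match(pairs$site1, res$resno)]
  r2t <- res$resid[match(pairs$site2, res$resno)]
  d <- sqrt((res$x[match(pairs$site1, res$resno)] -
               res$x[match(pairs$site2, res$resno)])^2 +
            (res$y[match(pairs$site1, res$resno)] -
               res$y[match(pairs$site2, res$resno)])^2 +
            (res$z[match(pairs$site1, res$resno)] -
               res$z[match(pairs$site2, res$resno)])^2)
  lim <- max_allowed_distance(r1t, r2t, spacer_length, reach_table)
  pol <- r2t %in% polar_residues
  within <- d <= lim
  set.seed(seed)
  n_over <- round(overlength_fraction * n_records)
  n_good <- n_records - n_over
  draw_pool <- function(pool_idx, n, bias) {
    if (n == 0) return(integer())
    want_polar <- runif(n) < bias
    p_pol <- pool_idx[pol[pool_idx]]
    p_non <- pool_idx[!pol[pool_idx]]
    vapply(want_polar, function(wp) {
      pool <- if (wp && length(p_pol)) p_pol
              else if (!wp && length(p_non)) p_non else pool_idx
      pool[sample.int(length(pool), 1)]
    }, integer(1))
  }
  idx_within <- which(within); idx_beyond <- which(!within)
  if (n_good > 0 && length(idx_within) == 0)
    abort("no within-limit candidate pairs", class = "photoxl_validation")
  if (n_over > 0 && length(idx_beyond) == 0)
    abort("no beyond-limit candidate pairs", class = "photoxl_validation")
  # contaminants emulate carbene/misassigned links: mostly non-polar targets
  ii <- c(draw_pool(idx_within, n_good, polar_bias),
          draw_pool(idx_beyond, n_over, 1 - polar_bias))
  is_over <- rep(c(FALSE, TRUE), c(n_good, n_over))
  err_sd <- ifelse(is_over, mass_error_sd[["contaminant"]],
                   mass_error_sd[["good"]])
  out <- crosslink_records(
    protein_id = structure$protein_id,
    site1 = pairs$site1[ii], site2 = pairs$site2[ii],
    residue2_type = r2t[ii],
    link_class = "cross-link",
    psm_count = rpois(n_records, 3) + 1L,
    mass_error_ppm = rnorm(n_records, 0, err_sd),
    condition = condition)
  out$truth_overlength <- is_over
  out$truth_polar <- pol[ii]
  out
}
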