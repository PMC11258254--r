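# Distance mapping, histograms, enrichment, SASA, mass-error comparison.

test_that("C-alpha distances are symmetric, zero on the diagonal, and match helix trigonometry", {
  s <- generate_toy_structure("ideal-helix", 30)
  expect_equal(ca_distance(s, 7, 7), 0)
  expect_equal(ca_distance(s, 1, 2), helix_ca_distance(1), tolerance = 1e-10)
  expect_equal(ca_distance(s, 1, 2), 3.8, tolerance = 0.05)
  set.seed(5)
  for (i in 1:8) {
    ab <- sample(30, 2)
    expect_equal(ca_distance(s, ab[1], ab[2]), ca_distance(s, ab[2], ab[1]))
  }
  expect_error(ca_distance(s, 1, 999), class = "photoxl_missing_site")
})

test_that("distances are invariant under rigid transforms of the structure", {
  s <- generate_toy_structure("ideal-helix", 20)
  set.seed(11)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  R <- Rx %*% Rz
  shift <- runif(3, -50, 50)
  xyz <- as.matrix(s$residues[, c("x", "y", "z")]) %*% t(R) +
    matrix(shift, nrow(s$residues), 3, byrow = TRUE)
  s2 <- structure_model(transform(s$residues, x = xyz[, 1], y = xyz[, 2],
                                  z = xyz[, 3]))
  for (pair in list(c(1, 5), c(3, 17), c(2, 20))) {
    expect_equal(ca_distance(s2, pair[1], pair[2]),
                 ca_distance(s, pair[1], pair[2]), tolerance = 1e-9)
  }
})

test_that("maximally allowed distances come from the reach table and are symmetric", {
  expect_equal(max_allowed_distance("K", "G", 3.9), 11.3)
  zero <- c(K = 0, E = 0)
  expect_equal(max_allowed_distance("K", "E", 3.9, zero), 3.9)
  expect_equal(max_allowed_distance("K", "E"), max_allowed_distance("E", "K"))
  expect_error(max_allowed_distance("K", "Z"), class = "photoxl_validation")
})

test_that("cross-link mapping flags exactly the injected over-length fraction", {
  hp <- generate_toy_structure("helix-hairpin", 40)
  cl0 <- simulate_crosslink_dataset(hp, overlength_fraction = 0,
                                    n_records = 60, seed = 2)
  mp0 <- map_crosslinks(cl0, hp)
  expect_equal(sum(mp0$over_length), 0)

  cl <- simulate_crosslink_dataset(hp, overlength_fraction = 0.2,
                                   n_records = 100, seed = 3)
  mp <- map_crosslinks(cl, hp)
  expect_equal(mean(mp$over_length), 0.2)
  expect_equal(mp$over_length, cl$truth_overlength)
  # flag is exactly normalized > 0, no hidden tolerance
  expect_equal(mp$over_length, mp$normalized > 0)
  expect_equal(attr(mp, "summary")$mapped, 100)
})

test_that("records at residues absent from the structure land in the unmapped report", {
  hp <- generate_toy_structure("helix-hairpin", 40)
  recs <- crosslink_records("toy", c(1, 1), c(5, 300), c("E", "E"))
  mp <- map_crosslinks(recs, hp)
  expect_equal(mp$mapped, c(TRUE, FALSE))
  expect_equal(attr(mp, "summary")$unmapped, 1)
  mp_empty <- map_crosslinks(crosslink_records(character(), integer(),
                                               integer(), character()), hp)
  expect_equal(nrow(mp_empty), 0)
})

test_that("distance histograms bin half-open at zero and conserve mass", {
  res <- tibble::tibble(mapped = TRUE, normalized = c(-6, -2, 3),
                        psm_count = c(2L, 1L, 4L))
  h <- distance_distribution(res, bin_width = 4)
  expect_equal(h$bin_lo, c(-8, -4, 0))
  expect_equal(h$count, c(1, 1, 1))
  expect_equal(sum(distance_distribution(res, weight = "psm")$count), 7)
  # mass conserved under any bin width
  for (bw in c(1, 2.5, 4, 10)) {
    expect_equal(sum(distance_distribution(res, bin_width = bw)$count), 3)
  }
  expect_equal(nrow(distance_distribution(res[0, ])), 0)
  expect_error(distance_distribution(res, bin_width = 0),
               class = "photoxl_validation")
})

test_that("residue enrichment matches hand arithmetic and is null under proportional sampling", {
  # toy sequence: 10% Glu; records 50% to Glu -> ratio 5
  seqstr <- paste0(strrep("A", 9), "E", strrep("G", 8), "ES")  # 2 E in 20
  recs <- crosslink_records("p", rep(1, 10), c(10, 19, 10, 19, 10, 1, 2, 3,
                                               4, 5),
                            c(rep("E", 5), rep("A", 5)))
  en <- residue_enrichment(recs, seqstr)
  expect_equal(en$ratio[en$residue == "E"], 0.5 / 0.1)

  # proportional sampling: all ratios ~ 1
  set.seed(9)
  seq2 <- paste(sample(c("A", "E", "K", "S", "V"), 200, replace = TRUE,
                       prob = c(0.3, 0.2, 0.2, 0.2, 0.1)), collapse = "")
  aa <- strsplit(seq2, "")[[1]]
  sites <- sample(200, 5000, replace = TRUE)
  recs2 <- crosslink_records("p", rep(1, 5000), sites, aa[sites])
  en2 <- residue_enrichment(recs2, seq2)
  expect_true(all(abs(en2$ratio - 1) < 0.25))
  expect_equal(sum(en2$observed_fraction), 1)

  expect_error(residue_enrichment(crosslink_records("p", 1, 999, "E"),
                                  "AAAA"),
               class = "photoxl_validation")
})

test_that("a synthetic diazo-biased dataset enriches polar targets", {
  hp <- generate_toy_structure("helix-hairpin", 60)
  cl <- simulate_crosslink_dataset(hp, polar_bias = 1, n_records = 200,
                                   seed = 4)
  seqstr <- paste(hp$residues$resid, collapse = "")
  en <- residue_enrichment(cl, seqstr)
  pol <- en[en$residue %in% c("D", "E", "Y"), ]
  expect_true(all(pol$ratio > 1))
})

test_that("SASA of an isolated sphere matches the analytic area", {
  one <- sasa_profile(tibble::tibble(x = 0, y = 0, z = 0, radius = 1.9),
                      probe_radius = 1.4)
  expect_equal(one$sasa, 4 * pi * 3.3^2, tolerance = 0.02)
  expect_error(sasa_profile(tibble::tibble(x = numeric(), y = numeric(),
                                           z = numeric(),
                                           radius = numeric())),
               class = "photoxl_validation")
})

test_that("coincident spheres are deduplicated so the total equals one sphere", {
  two <- tibble::tibble(x = c(0, 0), y = c(0, 0), z = c(0, 0),
                        radius = c(1.9, 1.9))
  expect_warning(out <- sasa_profile(two), "coincident")
  expect_equal(sum(out$sasa), 4 * pi * 3.3^2, tolerance = 1e-9)
})

test_that("interior residues of the helix hairpin are more buried than termini", {
  hp <- generate_toy_structure("helix-hairpin", 40)
  sp <- sasa_profile(hp)
  expect_true(all(sp$sasa >= 0))
  interior <- mean(sp$rel_sasa[sp$resno %in% 15:25])
  termini <- mean(sp$rel_sasa[sp$resno %in% c(1, 2, 39, 40)])
  expect_lt(interior, termini)
})

test_that("mass-error statistics separate contaminated groups and degrade gracefully", {
  set.seed(13)
  recs <- crosslink_records("p", rep(1, 120), rep(2, 120),
                            rep(c("E", "I"), each = 60),
                            mass_error_ppm = c(rnorm(60, 0, 2),
                                               rnorm(60, 0, 5)))
  ms <- mass_error_stats(recs, seed = 2)
  g <- ms$groups
  expect_gt(g$sd[g$group == "non-polar"], g$sd[g$group == "polar"])
  expect_true(ms$difference$defined)
  expect_gt(ms$difference$estimate, 0)

  # identical groups: difference ~ 0
  recs2 <- crosslink_records("p", rep(1, 40), rep(2, 40),
                             rep(c("E", "I"), 20),
                             mass_error_ppm = rep(c(-1, 1), 20))
  ms2 <- mass_error_stats(recs2)
  expect_equal(ms2$difference$estimate, 0, tolerance = 1e-12)

  # empty polar group: undefined, no crash
  recs3 <- crosslink_records("p", 1:3, 4:6, c("I", "V", "L"),
                             mass_error_ppm = c(1, 2, 3))
  expect_false(mass_error_stats(recs3)$difference$defined)
})

test_that("Thr-involving links are excluded from restraint use by default", {
  hp <- generate_toy_structure("helix-hairpin", 40)
  recs <- crosslink_records("toy", c(1, 1), c(11, 8), c("T", "D"))
  mp <- map_crosslinks(recs, hp)
  expect_false(mp$use_as_restraint[1])
  expect_true(mp$use_as_restraint[2])
  mp2 <- map_crosslinks(recs, hp, exclude_thr = FALSE)
  expect_true(all(mp2$use_as_restraint))
})
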