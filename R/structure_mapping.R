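# Mapping cross-links onto protein structures: C-alpha distances,
# maximally allowed distances, over-length flagging, distance histograms,
# residue-type enrichment, solvent accessibility, mass-error comparison.

#' Structure model
#'
#' Per-residue C-alpha coordinates plus (optionally) a heavy-atom table
#' for solvent-accessibility calculations. Residues are keyed by
#' chain-qualified author numbering (1-based).
#'
#' @param residues tibble with columns `chain`, `resno`, `resid`
#'   (one-letter amino-acid code), `x`, `y`, `z` (C-alpha coordinates, A).
#' @param atoms optional tibble with columns `chain`, `resno`, `resid`,
#'   `name`, `x`, `y`, `z`, `radius` (van der Waals radius, A).
#' @param protein_id label carried into derived records.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(residues, atoms = NULL, protein_id = "protein") {
  residues <- as_tibble(residues)
  need <- c("chain", "resno", "resid", "x", "y", "z")
  if (!all(need %in% names(residues)))
    abort(paste("residues needs columns", paste(need, collapse = ", ")),
          class = "photoxl_validation")
  if (anyDuplicated(residues[, c("chain", "resno")]))
    abort("duplicate (chain, resno) keys", class = "photoxl_validation")
  if (!all(is.finite(unlist(residues[, c("x", "y", "z")]))))
    abort("coordinates must be finite", class = "photoxl_validation")
  if (!is.null(atoms)) atoms <- as_tibble(atoms)
  structure(list(residues = residues, atoms = atoms,
                 protein_id = protein_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model '%s': %d residues, %s atoms\n", x$protein_id,
              nrow(x$residues),
              if (is.null(x$atoms)) "no" else nrow(x$atoms)))
  invisible(x)
}

# van der Waals radii by element (A); used when reading coordinate files.
element_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                   P = 1.80)

#' Read a structure from a PDB or mmCIF file
#'
#' Thin wrapper over [bio3d::read.pdb()] / [bio3d::read.cif()] that
#' extracts per-residue C-alpha coordinates and a heavy-atom table with
#' van der Waals radii. Only the first model is used; numbering follows
#' the author (PDB) scheme.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param protein_id label; defaults to the file name.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, protein_id = NULL) {
  if (!file.exists(path))
    abort(paste("no such file:", path), class = "photoxl_validation")
  if (is.null(protein_id))
    protein_id <- sub("\\.(pdb|cif)$", "", basename(path), ignore.case = TRUE)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- as_tibble(pdb$atom[pdb$atom$type == "ATOM", ])
  if (nrow(at) == 0)
    abort("no ATOM records", class = "photoxl_validation")
  elem <- ifelse(is.na(at$elesy) | at$elesy == "",
                 substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy)
  atoms <- tibble(chain = at$chain, resno = at$resno,
                  resid = bio3d::aa321(at$resid), name = at$elety,
                  x = at$x, y = at$y, z = at$z,
                  radius = unname(element_radii[elem]))
  atoms$radius[is.na(atoms$radius)] <- 1.70
  ca <- atoms[at$elety == "CA", ]
  residues <- ca[, c("chain", "resno", "resid", "x", "y", "z")]
  structure_model(residues, atoms, protein_id)
}

find_residue <- function(structure, site, chain = NULL) {
  res <- structure$residues
  if (is.null(chain)) chain <- res$chain[1]
  i <- which(res$chain == chain & res$resno == site)
  if (length(i) != 1)
    abort(sprintf("residue %s:%d absent from structure (no C-alpha)",
                  chain, site),
          class = "photoxl_missing_site")
  res[i, ]
}

#' C-alpha to C-alpha distance
#'
#' Intra-chain Cartesian distance between the C-alpha atoms of two
#' residues (the proteins are treated as strictly monomeric).
#'
#' @param structure a [structure_model()].
#' @param site1,site2 author residue numbers.
#' @param chain chain id; defaults to the first chain.
#' @return distance, A.
#' @export
ca_distance <- function(structure, site1, site2, chain = NULL) {
  r1 <- find_residue(structure, site1, chain)
  r2 <- find_residue(structure, site2, chain)
  sqrt((r1$x - r2$x)^2 + (r1$y - r2$y)^2 + (r1$z - r2$z)^2)
}

#' Per-residue side-chain reach table
#'
#' Maximal C-alpha-to-reactive-atom extension of each residue type (A),
#' used to build maximally allowed cross-link distances. The values are a
#' configuration default derived from extended side-chain geometry and can
#' be overridden wholesale.
#'
#' @return Named numeric vector over the 20 one-letter codes.
#' @export
default_reach <- function() {
  c(G = 1.0, A = 1.5, S = 2.4, C = 2.8, T = 2.1, V = 2.0, P = 1.9,
    L = 3.1, I = 3.1, M = 4.1, N = 2.9, D = 2.5, Q = 4.0, E = 3.7,
    K = 6.4, R = 7.3, H = 4.0, F = 4.3, W = 5.3, Y = 6.5)
}

#' Maximally allowed C-alpha distance of a cross-link
#'
#' Geometric upper bound on the C-alpha separation compatible with the
#' cross-linker: side-chain reach of the anchor residue + spacer length +
#' reach of the target residue.
#'
#' @param res1_type,res2_type one-letter residue codes.
#' @param spacer_length spacer arm of the cross-linker, A (default 3.9,
#'   the diazirine arm of SDA).
#' @param reach_table named reach values, A; see [default_reach()].
#' @return distance bound, A.
#' @export
max_allowed_distance <- function(res1_type, res2_type, spacer_length = 3.9,
                                 reach_table = default_reach()) {
  bad <- setdiff(c(res1_type, res2_type), names(reach_table))
  if (length(bad))
    abort(paste("unknown residue code(s):", paste(unique(bad), collapse = ", ")),
          class = "photoxl_validation")
  unname(reach_table[res1_type] + spacer_length + reach_table[res2_type])
}

#' Cross-link record table constructor
#'
#' @param protein_id protein label.
#' @param site1 anchor-residue (Lys) author numbers, >= 1.
#' @param site2 target-residue author numbers, >= 1.
#' @param residue2_type one-letter code of the target residue.
#' @param link_class `"cross-link"` or `"loop-link"`.
#' @param psm_count peptide-spectrum-match counts, >= 0.
#' @param mass_error_ppm precursor mass errors, ppm.
#' @param condition power-condition label (e.g. `"low"`, `"high"`).
#' @return A tibble of class `crosslink_records`.
#' @export
crosslink_records <- function(protein_id, site1, site2, residue2_type,
                              link_class = "cross-link", psm_count = 1L,
                              mass_error_ppm = NA_real_, condition = "low") {
  out <- tibble(protein_id = protein_id, site1 = as.integer(site1),
                site2 = as.integer(site2), residue2_type = residue2_type,
                link_class = link_class, psm_count = as.integer(psm_count),
                mass_error_ppm = mass_error_ppm, condition = condition)
  if (nrow(out) > 0) {
    if (any(out$site1 < 1) || any(out$site2 < 1))
      abort("site indices must be >= 1", class = "photoxl_validation")
    if (any(out$psm_count < 0))
      abort("psm_count must be >= 0", class = "photoxl_validation")
    if (!all(out$link_class %in% c("cross-link", "loop-link")))
      abort("link_class must be 'cross-link' or 'loop-link'",
            class = "photoxl_validation")
  }
  class(out) <- c("crosslink_records", class(out))
  out
}

#' Map cross-links onto a structure
#'
#' Computes for each record the C-alpha distance, the maximally allowed
#' distance, the normalized distance (`calc - max_allowed`; negative =
#' satisfied), and the over-length flag (`normalized > 0`, no hidden
#' tolerance). Records whose sites are absent from the structure are
#' reported as unmapped, never dropped silently. The anchor residue type
#' is taken from the structure at `site1`.
#'
#' @param records a [crosslink_records()] table.
#' @param structure a [structure_model()].
#' @param spacer_length,reach_table see [max_allowed_distance()].
#' @param exclude_thr mark Thr-involving links as unusable for restraints
#'   (`use_as_restraint = FALSE`)? Default `TRUE`: solvent-exposed Thr
#'   links are enriched in false positives.
#' @return A tibble: the records plus `mapped`, `calc_distance`,
#'   `max_allowed`, `normalized`, `over_length`, `use_as_restraint`;
#'   summary counts in `attr(, "summary")`.
#' @export
map_crosslinks <- function(records, structure, spacer_length = 3.9,
                           reach_table = default_reach(),
                           exclude_thr = TRUE) {
  records <- as_tibble(records)
  n <- nrow(records)
  out <- dplyr::mutate(records, mapped = FALSE, calc_distance = NA_real_,
                       max_allowed = NA_real_, normalized = NA_real_,
                       over_length = NA, res1_type = NA_character_)
  for (i in seq_len(n)) {
    r1 <- tryCatch(find_residue(structure, records$site1[i]),
                   error = function(e) NULL)
    r2 <- tryCatch(find_residue(structure, records$site2[i]),
                   error = function(e) NULL)
    if (is.null(r1) || is.null(r2)) next
    d <- sqrt((r1$x - r2$x)^2 + (r1$y - r2$y)^2 + (r1$z - r2$z)^2)
    out$mapped[i] <- TRUE
    out$res1_type[i] <- r1$resid
    out$calc_distance[i] <- d
    out$max_allowed[i] <- max_allowed_distance(r1$resid,
                                               records$residue2_type[i],
                                               spacer_length, reach_table)
    out$normalized[i] <- d - out$max_allowed[i]
    out$over_length[i] <- out$normalized[i] > 0
  }
  out$use_as_restraint <- out$mapped &
    !(exclude_thr & (out$residue2_type == "T" |
                       dplyr::coalesce(out$res1_type == "T", FALSE)))
  attr(out, "summary") <- list(
    n = n, mapped = sum(out$mapped), unmapped = sum(!out$mapped),
    over_length = sum(out$over_length, na.rm = TRUE))
  out
}

#' Histogram of normalized cross-link distances
#'
#' Bins the normalized distances (`calc - max_allowed`) into half-open
#' bins `[lo, hi)` anchored at 0.
#'
#' @param results output of [map_crosslinks()] (unmapped rows are
#'   ignored).
#' @param bin_width bin width, A (default 4).
#' @param weight `"records"` (count links) or `"psm"` (sum PSM counts).
#' @return A tibble with `bin_lo`, `bin_hi`, `count`.
#' @export
distance_distribution <- function(results, bin_width = 4,
                                  weight = c("records", "psm")) {
  weight <- match.arg(weight)
  if (bin_width <= 0)
    abort("bin_width must be > 0", class = "photoxl_validation")
  x <- results$normalized[results$mapped %in% TRUE]
  w <- if (weight == "psm") results$psm_count[results$mapped %in% TRUE]
       else rep(1, length(x))
  if (length(x) == 0)
    return(tibble(bin_lo = numeric(), bin_hi = numeric(), count = numeric()))
  idx <- floor(x / bin_width)
  agg <- tapply(w, idx, sum)
  lo <- as.numeric(names(agg)) * bin_width
  tibble(bin_lo = lo, bin_hi = lo + bin_width, count = as.numeric(agg))
}

#' Residue-type enrichment of cross-links over natural abundance
#'
#' Compares the residue-type composition of cross-linked (or loop-linked)
#' target sites with the residue-type composition of the full sequence,
#' separately per link class and power condition. The natural-abundance
#' denominator is every residue of the supplied sequence.
#'
#' @param records a [crosslink_records()] table.
#' @param sequence protein sequence (single character string, or an
#'   `AAStringSet`/named vector of length 1).
#' @param weight `"records"` or `"psm"` (weight observations by PSM
#'   count).
#' @return A tibble with `link_class`, `condition`, `residue`,
#'   `observed_fraction`, `natural_abundance`, `ratio`.
#' @export
residue_enrichment <- function(records, sequence,
                               weight = c("records", "psm")) {
  weight <- match.arg(weight)
  records <- as_tibble(records)
  sequence <- as_sequence_string(sequence)
  aa <- strsplit(sequence, "")[[1]]
  if (any(records$site2 > length(aa)))
    abort("records reference residues beyond the sequence length",
          class = "photoxl_validation")
  nat <- table(factor(aa, levels = sort(unique(aa)))) / length(aa)
  w <- if (weight == "psm") records$psm_count else rep(1, nrow(records))
  grp <- dplyr::group_by(dplyr::mutate(records, .w = w),
                         .data$link_class, .data$condition)
  dplyr::reframe(grp, {
    obs <- tapply(.data$.w, .data$residue2_type, sum)
    obs <- obs / sum(obs)
    tibble(residue = names(obs),
           observed_fraction = as.numeric(obs),
           natural_abundance = as.numeric(nat[names(obs)]),
           ratio = as.numeric(obs) / as.numeric(nat[names(obs)]))
  })
}

as_sequence_string <- function(sequence) {
  if (inherits(sequence, "XStringSet")) sequence <- as.character(sequence)[1]
  if (is.character(sequence) && length(sequence) >= 1) sequence <- sequence[[1]]
  if (!is.character(sequence) || nchar(sequence) == 0)
    abort("sequence must be a nonempty character string",
          class = "photoxl_validation")
  toupper(sequence)
}

# Default polarity grouping of cross-link target residues: the
# diazo-reactive polar set (carboxylates, hydroxyls, plus His/Arg).
polar_residues <- c("D", "E", "Y", "S", "T", "H", "R")

#' Precursor mass-error comparison by target-residue polarity
#'
#' Descriptive statistics of precursor mass errors for cross-links to
#' polar versus non-polar residues, with a bootstrap interval on the
#' difference in group mean absolute error. Incorrectly assigned
#' non-polar links tend to carry larger mass errors.
#'
#' @param records a [crosslink_records()] table with `mass_error_ppm`.
#' @param polar_set one-letter codes treated as polar.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed of the bootstrap.
#' @return A list with `groups` (tibble: group, n, mean, sd, mean_abs)
#'   and `difference` (list: `estimate` = non-polar minus polar mean
#'   absolute error, `ci` 95% percentile interval, `defined`).
#' @export
mass_error_stats <- function(records, polar_set = polar_residues,
                             n_boot = 1000, seed = 1) {
  records <- as_tibble(records)
  records <- records[is.finite(records$mass_error_ppm), ]
  grp <- ifelse(records$residue2_type %in% polar_set, "polar", "non-polar")
  groups <- dplyr::reframe(
    dplyr::group_by(tibble(group = grp, err = records$mass_error_ppm),
                    .data$group),
    n = dplyr::n(), mean = mean(.data$err), sd = sd(.data$err),
    mean_abs = mean(abs(.data$err)))
  ep <- records$mass_error_ppm[grp == "polar"]
  en <- records$mass_error_ppm[grp == "non-polar"]
  if (length(ep) < 2 || length(en) < 2) {
    return(list(groups = groups,
                difference = list(estimate = NA_real_, ci = c(NA, NA),
                                  defined = FALSE)))
  }
  est <- mean(abs(en)) - mean(abs(ep))
  boot <- local({
    set.seed(seed)
    replicate(n_boot, mean(abs(sample(en, replace = TRUE))) -
                mean(abs(sample(ep, replace = TRUE))))
  })
  list(groups = groups,
       difference = list(estimate = est,
                         ci = unname(quantile(boot, c(0.025, 0.975))),
                         defined = TRUE))
}

#' Per-residue solvent-accessible surface area
#'
#' Shrake-Rupley SASA with golden-spiral quadrature over each atom's
#' expanded sphere (radius + probe). For structures carrying only
#' C-alpha atoms, a coarse single-sphere-per-residue approximation is
#' used and flagged. Exactly coincident atoms of equal radius are
#' deduplicated (with a warning) before quadrature. Relative SASA divides
#' by a per-residue-type reference maximum.
#'
#' @param structure a [structure_model()] with an atom table, or a bare
#'   atom tibble (`x`, `y`, `z`, `radius`).
#' @param probe_radius solvent probe radius, A (default 1.4, water).
#' @param n_points quadrature points per atom (default 242).
#' @return A tibble with `chain`, `resno`, `resid`, `sasa` (A^2),
#'   `rel_sasa`; `attr(, "approximation")` is `"ca-sphere"` when the
#'   coarse model was used. For a bare atom table, per-atom SASA.
#' @export
sasa_profile <- function(structure, probe_radius = 1.4, n_points = 242) {
  if (inherits(structure, "structure_model")) {
    atoms <- structure$atoms
    approximation <- "heavy-atom"
    if (is.null(atoms) || nrow(atoms) == 0 ||
        all(atoms$name == "CA")) {
      # coarse fallback: one sphere per residue at the C-alpha
      atoms <- dplyr::mutate(structure$residues, name = "CA", radius = 3.3)
      approximation <- "ca-sphere"
    }
    per_atom <- atom_sasa(atoms, probe_radius, n_points)
    res <- dplyr::summarise(
      dplyr::group_by(per_atom, .data$chain, .data$resno, .data$resid),
      sasa = sum(.data$sasa), .groups = "drop")
    ref <- unname(max_sasa_ref[res$resid])
    ref[is.na(ref)] <- stats::median(max_sasa_ref)
    res$rel_sasa <- res$sasa / ref
    attr(res, "approximation") <- approximation
    res
  } else {
    atom_sasa(as_tibble(structure), probe_radius, n_points)
  }
}

# Reference maximum SASA per residue type (theoretical Gly-X-Gly values,
# A^2); unknown types fall back to the median.
max_sasa_ref <- local({
  v <- c(A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
         G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
         P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)
  v
})

atom_sasa <- function(atoms, probe_radius, n_points) {
  if (nrow(atoms) == 0)
    abort("no atoms", class = "photoxl_validation")
  if (!all(c("x", "y", "z", "radius") %in% names(atoms)))
    abort("atom table needs x, y, z, radius", class = "photoxl_validation")
  key <- paste(round(atoms$x, 6), round(atoms$y, 6), round(atoms$z, 6),
               round(atoms$radius, 6))
  if (anyDuplicated(key)) {
    warn("exactly coincident atoms deduplicated for SASA")
    atoms <- atoms[!duplicated(key), ]
  }
  n <- nrow(atoms)
  pts <- golden_spiral_points(n_points)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- atoms$radius + probe_radius
  sasa <- numeric(n)
  # neighbor pruning via squared distances
  for (i in seq_len(n)) {
    di <- sqrt(rowSums((xyz - matrix(xyz[i, ], n, 3, byrow = TRUE))^2))
    nb <- which(di < rad[i] + rad & seq_len(n) != i)
    if (length(nb) == 0) {
      sasa[i] <- 4 * pi * rad[i]^2
      next
    }
    test <- pts * rad[i]
    test <- sweep(test, 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (test[, 1] - xyz[j, 1])^2 + (test[, 2] - xyz[j, 2])^2 +
        (test[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 >= (rad[j] - 1e-10)^2
      if (!any(exposed)) break
    }
    sasa[i] <- 4 * pi * rad[i]^2 * mean(exposed)
  }
  atoms$sasa <- sasa
  atoms
}

golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
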