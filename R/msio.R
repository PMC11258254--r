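# Mass utilities (monoisotopic mass, adduct m/z) and file I/O for the
# CSV dialects, FASTA and report formats the pipeline consumes.

# Monoisotopic atomic masses (Da), CODATA/AME values.
monoisotopic_masses <- c(
  C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163, Na = 22.9897692809, K = 38.96370668)

electron_mass <- 0.000548579909

#' Molecular formula
#'
#' Parses a Hill-style formula string (e.g. `"C13H17N3O6"`) or accepts a
#' named count vector. Supported elements: C, H, N, O, S, P, Na, K.
#'
#' @param x formula string or named integer vector.
#' @return A named integer vector of class `molecular_formula`.
#' @examples
#' molecular_formula("C13H17N3O6")
#' @export
molecular_formula <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
    toks <- regmatches(x, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(x))
      abort(paste("cannot parse formula:", x), class = "photoxl_validation")
    el <- gsub("[0-9]", "", toks)
    ct <- as.integer(ifelse(gsub("[A-Za-z]", "", toks) == "", "1",
                            gsub("[A-Za-z]", "", toks)))
    counts <- tapply(ct, el, sum)
    x <- setNames(as.integer(counts), names(counts))
  }
  if (is.null(names(x)) && length(x) > 0)
    abort("formula vector must be named", class = "photoxl_validation")
  if (any(x < 0) || any(x != round(x)))
    abort("element counts must be nonnegative integers",
          class = "photoxl_validation")
  bad <- setdiff(names(x), names(monoisotopic_masses))
  if (length(bad))
    abort(paste("unsupported element(s):", paste(bad, collapse = ", ")),
          class = "photoxl_validation")
  structure(setNames(as.integer(x), names(x)), class = "molecular_formula")
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula a [molecular_formula()] (or something coercible).
#' @return mass, Da.
#' @examples
#' monoisotopic_mass(molecular_formula("H2O"))
#' @export
monoisotopic_mass <- function(formula) {
  if (!inherits(formula, "molecular_formula"))
    formula <- molecular_formula(formula)
  if (length(formula) == 0) return(0)
  sum(monoisotopic_masses[names(formula)] * as.integer(formula))
}

#' Adduct m/z of a molecular formula
#'
#' Adds the cation mass (minus the electron carried away) and divides by
#' the charge.
#'
#' @param formula a [molecular_formula()].
#' @param adduct `"M+H"`, `"M+Na"` or `"M+K"`.
#' @param charge positive integer charge (default 1).
#' @return m/z.
#' @examples
#' adduct_mz(molecular_formula("C13H17N3O6"), "M+H")   # 312.118
#' @export
adduct_mz <- function(formula, adduct = c("M+H", "M+Na", "M+K"),
                      charge = 1) {
  adduct <- match.arg(adduct)
  if (charge < 1 || charge != round(charge))
    abort("charge must be a positive integer", class = "photoxl_validation")
  cat_mass <- switch(adduct,
    "M+H" = monoisotopic_masses[["H"]],
    "M+Na" = monoisotopic_masses[["Na"]],
    "M+K" = monoisotopic_masses[["K"]])
  (monoisotopic_mass(formula) + charge * (cat_mass - electron_mass)) / charge
}

# ---- CSV dialects -------------------------------------------------------

#' Read and write MRM trace tables
#'
#' Canonical columns: `species`, `power_mw_cm2`, `time_s`, `intensity`,
#' `replicate_id`. Round-trips with [simulate_mrm_traces()] output.
#'
#' @param x trace tibble.
#' @param path file path.
#' @return `read_mrm_csv()`: a tibble.
#' @export
write_mrm_csv <- function(x, path) {
  readr::write_csv(x[, c("species", "power_mw_cm2", "time_s", "intensity",
                         "replicate_id")], path)
  invisible(path)
}

#' @rdname write_mrm_csv
#' @export
read_mrm_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           species = "c", power_mw_cm2 = "d", time_s = "d",
                           intensity = "d", replicate_id = "c"))
  check_schema(out, list(
    species = function(v) v %in% c("A", "B", "D"),
    time_s = function(v) is.finite(v) & v >= 0,
    intensity = is.finite,
    power_mw_cm2 = function(v) is.finite(v) & v >= 0))
  out
}

#' Read and write yield tables
#'
#' Canonical columns: `power_mw_cm2`, `time_s`, `yield`, `residue`.
#'
#' @param x yield tibble.
#' @param path file path.
#' @return `read_yield_csv()`: a tibble.
#' @export
write_yield_csv <- function(x, path) {
  readr::write_csv(x[, c("power_mw_cm2", "time_s", "yield", "residue")],
                   path)
  invisible(path)
}

#' @rdname write_yield_csv
#' @export
read_yield_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           power_mw_cm2 = "d", time_s = "d", yield = "d",
                           residue = "c"))
  check_schema(out, list(
    yield = function(v) is.finite(v) & v >= 0 & v <= 1,
    power_mw_cm2 = function(v) is.finite(v) & v >= 0,
    time_s = function(v) is.finite(v) & v >= 0))
  out
}

#' Read and write canonical cross-link tables
#'
#' Canonical columns: `protein_id`, `site1`, `site2`, `residue2_type`,
#' `link_class`, `psm_count`, `mass_error_ppm`, `condition`. Schema
#' violations are collected and reported together with their row numbers.
#'
#' @param x a [crosslink_records()] tibble.
#' @param path file path.
#' @return `read_crosslinks_csv()`: a `crosslink_records` tibble.
#' @export
write_crosslinks_csv <- function(x, path) {
  readr::write_csv(x[, c("protein_id", "site1", "site2", "residue2_type",
                         "link_class", "psm_count", "mass_error_ppm",
                         "condition")], path)
  invisible(path)
}

#' @rdname write_crosslinks_csv
#' @export
read_crosslinks_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           protein_id = "c", site1 = "i", site2 = "i",
                           residue2_type = "c", link_class = "c",
                           psm_count = "i", mass_error_ppm = "d",
                           condition = "c"))
  check_schema(out, list(
    site1 = function(v) !is.na(v) & v >= 1,
    site2 = function(v) !is.na(v) & v >= 1,
    psm_count = function(v) !is.na(v) & v >= 0,
    link_class = function(v) v %in% c("cross-link", "loop-link")))
  crosslink_records(out$protein_id, out$site1, out$site2,
                    out$residue2_type, out$link_class, out$psm_count,
                    out$mass_error_ppm, out$condition)
}

# Validate columns against predicates; collect every violation (with row
# numbers) into a single error rather than failing on the first.
check_schema <- function(df, rules) {
  msgs <- character()
  for (col in names(rules)) {
    if (!col %in% names(df)) {
      msgs <- c(msgs, paste("missing column", col))
      next
    }
    ok <- rules[[col]](df[[col]])
    if (!all(ok)) {
      rows <- which(!ok)
      msgs <- c(msgs, sprintf("column %s invalid at row(s) %s", col,
                              paste(head(rows, 10), collapse = ", ")))
    }
  }
  if (length(msgs))
    abort(paste0("schema violations:\n  ", paste(msgs, collapse = "\n  ")),
          class = "photoxl_schema")
  invisible(df)
}

#' Read a pLink2-flavoured cross-link export
#'
#' Parses the bracketed-site strings of pLink2-style CSV exports. The
#' `Proteins` column carries protein-level sites directly
#' (`"NAME(241)-NAME(562)"` for cross-links, `"NAME(245)(249)"` for
#' loop-links). When only the `Peptide` column (`"SEQ1(3)-SEQ2(5)"`) is
#' present, peptides are located in the supplied sequences and absolute
#' residue numbers computed as match start + site - 1.
#'
#' @param path CSV with columns `Proteins` and/or `Peptide`, optionally
#'   `Peptide_Type`, `PSM` (or `#PSM`), `Mass_Error_ppm`, `Condition`.
#' @param sequences named character vector (or `AAStringSet`) of protein
#'   sequences; required when absolute sites must be derived from
#'   peptides.
#' @return A [crosslink_records()] tibble; residue types are filled from
#'   `sequences` when available.
#' @export
read_plink2_csv <- function(path, sequences = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (inherits(sequences, "XStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  n <- nrow(raw)
  prot <- rep(NA_character_, n); s1 <- s2 <- rep(NA_integer_, n)
  cls <- rep("cross-link", n)
  errors <- character()
  for (i in seq_len(n)) {
    parsed <- NULL
    if ("Proteins" %in% names(raw) && !is.na(raw$Proteins[i]))
      parsed <- parse_plink_sites(raw$Proteins[i])
    if (is.null(parsed) && "Peptide" %in% names(raw)) {
      parsed <- parse_plink_peptide(raw$Peptide[i], sequences)
    }
    if (is.null(parsed)) {
      errors <- c(errors, sprintf("row %d: unparseable site string", i))
      next
    }
    prot[i] <- parsed$protein; s1[i] <- parsed$site1; s2[i] <- parsed$site2
    cls[i] <- parsed$link_class
  }
  if (length(errors))
    abort(paste0("pLink2 parse failures:\n  ",
                 paste(errors, collapse = "\n  ")),
          class = "photoxl_schema")
  if ("Peptide_Type" %in% names(raw))
    cls <- ifelse(grepl("loop", tolower(raw$Peptide_Type)), "loop-link", cls)
  psm <- if ("PSM" %in% names(raw)) raw$PSM
         else if ("#PSM" %in% names(raw)) raw[["#PSM"]] else rep(1L, n)
  err <- if ("Mass_Error_ppm" %in% names(raw)) raw$Mass_Error_ppm
         else rep(NA_real_, n)
  cond <- if ("Condition" %in% names(raw)) raw$Condition else rep("low", n)
  r2 <- rep(NA_character_, n)
  if (!is.null(sequences)) {
    hit <- prot %in% names(sequences)
    r2[hit] <- substr(sequences[prot[hit]], s2[hit], s2[hit])
  }
  crosslink_records(prot, s1, s2, r2, cls, as.integer(psm), err, cond)
}

# "NAME(241)-NAME(562)" or "NAME(245)(249)"
parse_plink_sites <- function(s) {
  s <- gsub("\\s", "", s)
  m <- regmatches(s, regexec("^([^()-]+)\\((\\d+)\\)-([^()-]+)\\((\\d+)\\)$", s))[[1]]
  if (length(m) == 5)
    return(list(protein = m[2], site1 = as.integer(m[3]),
                site2 = as.integer(m[5]), link_class = "cross-link"))
  m <- regmatches(s, regexec("^([^()-]+)\\((\\d+)\\)\\((\\d+)\\)$", s))[[1]]
  if (length(m) == 4)
    return(list(protein = m[2], site1 = as.integer(m[3]),
                site2 = as.integer(m[4]), link_class = "loop-link"))
  NULL
}

# "PEPTIDEA(3)-PEPTIDEB(5)" resolved against named sequences
parse_plink_peptide <- function(s, sequences) {
  if (is.null(sequences) || is.na(s)) return(NULL)
  s <- gsub("\\s", "", s)
  m <- regmatches(s, regexec("^([A-Z]+)\\((\\d+)\\)-([A-Z]+)\\((\\d+)\\)$", s))[[1]]
  if (length(m) != 5) return(NULL)
  locate <- function(pep) {
    for (nm in names(sequences)) {
      pos <- regexpr(pep, sequences[[nm]], fixed = TRUE)
      if (pos > 0) return(list(protein = nm, start = as.integer(pos)))
    }
    NULL
  }
  l1 <- locate(m[2]); l2 <- locate(m[4])
  if (is.null(l1) || is.null(l2) || l1$protein != l2$protein) return(NULL)
  list(protein = l1$protein,
       site1 = l1$start + as.integer(m[3]) - 1L,
       site2 = l2$start + as.integer(m[5]) - 1L,
       link_class = "cross-link")
}

# ---- FASTA and reports --------------------------------------------------

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' @param x a named list (scalars unboxed).
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
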