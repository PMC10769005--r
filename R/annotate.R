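# Theoretical lipid mass chemistry: elemental formulas per lipid class,
# monoisotopic masses, adduct m/z, 13C isotopologues, and ppm matching of
# picked peaks against a species table.

# Monoisotopic atomic masses (Da). 12C is exact by definition.
.monoisotopic_masses <- c(
  C  = 12,
  H  = 1.0078250319,
  N  = 14.0030740,
  O  = 15.9949146,
  P  = 30.9737615,
  Na = 22.9897693,
  K  = 38.9637065,
  Cl = 34.9688527
)

#' Mass constants used throughout the package
#'
#' Proton and electron masses and the 13C-12C mass difference (Da).
#' @name mass-constants
#' @keywords internal
NULL
PROTON_MASS   <- 1.00727646
ELECTRON_MASS <- 0.00054858
C13_SHIFT     <- 1.0033548

#' Parse an elemental formula string
#'
#' Converts a Hill-style formula such as `"C23H48NO7P"` into a named integer
#' vector of element counts. Only the elements relevant to glycero- and
#' sphingolipid adduct chemistry are supported (C, H, N, O, P, Na, K, Cl).
#'
#' @param formula A formula string or an already-parsed named numeric vector.
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C23H48NO7P")
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) || any(!names(formula) %in% names(.monoisotopic_masses)))
      stop_sddmark("formula vector must be named with supported elements")
    return(formula)
  }
  stopifnot(is.character(formula), length(formula) == 1)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)
  parts <- regmatches(formula, m)[[1]]
  parts <- parts[nzchar(parts)]
  if (!nzchar(formula) || sum(nchar(parts)) != nchar(formula))
    stop_sddmark("cannot parse formula '%s'", formula)
  elems <- sub("[0-9]*$", "", parts)
  counts <- as.integer(ifelse(grepl("[0-9]+$", parts),
                              sub("^[A-Za-z]+", "", parts), "1"))
  bad <- setdiff(elems, names(.monoisotopic_masses))
  if (length(bad))
    stop_sddmark("unsupported element(s): %s", paste(bad, collapse = ", "))
  out <- tapply(counts, elems, sum)
  storage.mode(out) <- "integer"
  out[order(names(out))]
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums monoisotopic atomic masses over the element counts of `formula`.
#'
#' @param formula Formula string or named count vector (see [parse_formula()]).
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")          # 18.0106
#' monoisotopic_mass("C23H48NO7P")   # 481.3168
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(counts * .monoisotopic_masses[names(counts)])
}

# Cation/anion mass offsets relative to the neutral molecule, electron mass
# included so the printed four-decimal calibrant values are reproduced.
.adduct_offsets <- c(
  "+H"  = PROTON_MASS,
  "+Na" = 22.9897693 - ELECTRON_MASS,
  "+K"  = 38.9637065 - ELECTRON_MASS,
  "-H"  = -PROTON_MASS,
  "+Cl" = 34.9688527 + ELECTRON_MASS
)

.adduct_polarity <- c("+H" = "positive", "+Na" = "positive", "+K" = "positive",
                      "-H" = "negative", "+Cl" = "negative")

normalize_adduct <- function(adduct) {
  a <- gsub("−", "-", adduct)           # unicode minus
  a <- gsub("^\\[M|\\]\\+?-?$", "", a)       # tolerate "[M+H]+" style
  a <- sub("\\]$", "", a)
  if (!a %in% names(.adduct_offsets))
    stop_sddmark("unsupported adduct '%s' (use one of %s)", adduct,
                 paste(names(.adduct_offsets), collapse = ", "))
  a
}

#' m/z of a singly charged adduct ion
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param adduct One of `"+H"`, `"+Na"`, `"+K"`, `"-H"`, `"+Cl"`.
#' @return Theoretical m/z of the singly charged ion.
#' @export
#' @examples
#' adduct_mz(monoisotopic_mass("C23H48NO7P"), "-H")   # 480.310 (LysoPE 18:0)
adduct_mz <- function(neutral_mass, adduct) {
  neutral_mass + .adduct_offsets[[normalize_adduct(adduct)]]
}

#' m/z of the k-th 13C isotopologue
#'
#' @param mz Monoisotopic m/z.
#' @param k Number of 13C substitutions (>= 0).
#' @return `mz + k * 1.0033548`.
#' @export
isotope_mz <- function(mz, k) {
  stopifnot(all(k >= 0))
  mz + k * C13_SHIFT
}

# Head-group composition rules: formula = C(n + dC) H(2n - 2d + dH) N(dN) O(dO) P,
# with n = total acyl (or base+acyl for SM) carbons and d = total double bonds.
.lipid_class_rules <- list(
  PC       = list(dC = 8, dH = 16, N = 1, O = 8),
  LPC      = list(dC = 8, dH = 18, N = 1, O = 7),
  PE       = list(dC = 5, dH = 10, N = 1, O = 8),
  LPE      = list(dC = 5, dH = 12, N = 1, O = 7),
  `PE-NMe2` = list(dC = 7, dH = 14, N = 1, O = 8),
  PA       = list(dC = 3, dH = 5,  N = 0, O = 8),
  LPA      = list(dC = 3, dH = 7,  N = 0, O = 7),
  cPA      = list(dC = 3, dH = 5,  N = 0, O = 6),
  PI       = list(dC = 9, dH = 15, N = 0, O = 13),
  SM       = list(dC = 5, dH = 13, N = 2, O = 6)
)

#' Elemental formula of a lipid species from class and C:DB shorthand
#'
#' Builds the molecular formula of a glycerophospholipid, lysolipid or
#' sphingomyelin from its class and the total carbon : double-bond notation
#' used in species names such as `"PC(32:0)"`. For SM the total counts follow
#' the combined base+acyl convention (`"SM(42:1)"`).
#'
#' @param class One of PC, LPC, PE, LPE, PE-NMe2, PA, LPA, cPA, PI, SM.
#' @param total_c Total chain carbons.
#' @param total_db Total chain double bonds.
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' lipid_class_formula("LPC", 18, 3)  # C26H48NO7P
#' lipid_class_formula("PC", 32, 0)   # C40H80NO8P
lipid_class_formula <- function(class, total_c, total_db) {
  if (!class %in% names(.lipid_class_rules))
    stop_sddmark("unsupported lipid class '%s'", class)
  stopifnot(total_c >= 0, total_db >= 0)
  r <- .lipid_class_rules[[class]]
  h <- 2 * total_c - 2 * total_db + r$dH
  if (h <= 0) stop_sddmark("negative hydrogen count for %s(%d:%d)", class, total_c, total_db)
  counts <- c(C = total_c + r$dC, H = h, N = r$N, O = r$O, P = 1)
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  counts[order(names(counts))]
}

#' Theoretical m/z of a named lipid species
#'
#' Convenience wrapper: class + C:DB -> formula -> adduct ion -> optional 13C
#' isotopologue.
#'
#' @inheritParams lipid_class_formula
#' @param adduct Adduct string (see [adduct_mz()]).
#' @param n13c Number of 13C substitutions (default 0).
#' @return Theoretical m/z.
#' @export
lipid_mz <- function(class, total_c, total_db, adduct, n13c = 0) {
  isotope_mz(adduct_mz(monoisotopic_mass(lipid_class_formula(class, total_c, total_db)),
                       adduct), n13c)
}

#' Expand a species table with adduct and isotopologue m/z values
#'
#' Takes a species table (columns `name`, and either `formula` or
#' `class`/`total_c`/`total_db`, plus `adduct` and optionally `n_isotopes`)
#' and returns one row per isotopologue with its theoretical m/z.
#'
#' @param species A data.frame species table.
#' @return data.frame with columns name, formula, adduct, n13c, theoretical_mz.
#' @export
expand_species_table <- function(species) {
  stopifnot(is.data.frame(species), "name" %in% names(species),
            "adduct" %in% names(species))
  if (!"formula" %in% names(species)) {
    stopifnot(all(c("class", "total_c", "total_db") %in% names(species)))
    species$formula <- vapply(seq_len(nrow(species)), function(i) {
      f <- lipid_class_formula(species$class[i], species$total_c[i], species$total_db[i])
      paste0(names(f), ifelse(f > 1, f, ""), collapse = "")
    }, character(1))
  }
  n_iso <- if ("n_isotopes" %in% names(species)) species$n_isotopes else rep(1L, nrow(species))
  rows <- lapply(seq_len(nrow(species)), function(i) {
    mono <- adduct_mz(monoisotopic_mass(species$formula[i]), species$adduct[i])
    k <- seq_len(n_iso[i]) - 1L
    data.frame(name = species$name[i], formula = species$formula[i],
               adduct = species$adduct[i], n13c = k,
               theoretical_mz = isotope_mz(mono, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$theoretical_mz), , drop = FALSE]
}

#' Match picked feature m/z values against a theoretical species table
#'
#' Each feature is matched to the nearest theoretical m/z within `tol_ppm`;
#' ties are broken toward the lower theoretical m/z. Features with no match
#' are kept and reported as `"unknown"`.
#'
#' @param feature_mz Numeric vector of picked feature m/z values.
#' @param species Species table (expanded with [expand_species_table()] if it
#'   lacks a `theoretical_mz` column).
#' @param tol_ppm Matching tolerance in ppm (default 10).
#' @return data.frame with one row per feature: feature_mz, name, adduct,
#'   n13c, theoretical_mz, error_ppm, tol_ppm.
#' @export
annotate_peaks <- function(feature_mz, species, tol_ppm = 10) {
  if (length(feature_mz) == 0)
    return(data.frame(feature_mz = numeric(), name = character(),
                      adduct = character(), n13c = integer(),
                      theoretical_mz = numeric(), error_ppm = numeric(),
                      tol_ppm = numeric(), stringsAsFactors = FALSE))
  if (!"theoretical_mz" %in% names(species))
    species <- expand_species_table(species)
  species <- species[order(species$theoretical_mz), , drop = FALSE]
  th <- species$theoretical_mz
  rows <- lapply(feature_mz, function(mz) {
    err <- abs(ppm_error(mz, th))
    j <- which(err == min(err))[1]          # ties -> lower theoretical m/z
    if (err[j] <= tol_ppm) {
      data.frame(feature_mz = mz, name = species$name[j],
                 adduct = species$adduct[j],
                 n13c = species$n13c[j] %||% 0L,
                 theoretical_mz = th[j],
                 error_ppm = ppm_error(mz, th[j]), tol_ppm = tol_ppm,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(feature_mz = mz, name = "unknown", adduct = NA_character_,
                 n13c = NA_integer_, theoretical_mz = NA_real_,
                 error_ppm = NA_real_, tol_ppm = tol_ppm,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Calibrant reference ions
#'
#' The recalibration reference ions used for the two polarities: PI(38:4)
#' [M-H]- in negative mode; PC(32:0) [M+Na]+, PC(34:1) [M+H]+ and
#' PC(34:1) [M+Na]+ (among others) in positive mode. Returned with their
#' theoretical m/z computed from composition rules.
#'
#' @param polarity `"positive"`, `"negative"` or `"both"` (default).
#' @return data.frame with name, class, total_c, total_db, adduct, polarity,
#'   theoretical_mz.
#' @export
calibrant_table <- function(polarity = c("both", "positive", "negative")) {
  polarity <- match.arg(polarity)
  tab <- data.frame(
    name     = c("PC(32:0)+Na", "PC(34:1)+H", "PC(34:1)+Na", "PC(32:0)+H",
                 "SM(34:1)+H", "PI(38:4)-H", "PI(34:1)-H", "PE(40:6)-H",
                 "PA(32:0)-H"),
    class    = c("PC", "PC", "PC", "PC", "SM", "PI", "PI", "PE", "PA"),
    total_c  = c(32L, 34L, 34L, 32L, 34L, 38L, 34L, 40L, 32L),
    total_db = c(0L, 1L, 1L, 0L, 1L, 4L, 1L, 6L, 0L),
    adduct   = c("+Na", "+H", "+Na", "+H", "+H", "-H", "-H", "-H", "-H"),
    polarity = c(rep("positive", 5), rep("negative", 4)),
    stringsAsFactors = FALSE
  )
  tab$theoretical_mz <- mapply(lipid_mz, tab$class, tab$total_c, tab$total_db, tab$adduct)
  if (polarity != "both") tab <- tab[tab$polarity == polarity, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
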