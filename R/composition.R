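# Elemental-composition arithmetic and monoisotopic mass computation.
# All downstream m/z values (Q1 precursors, the sialic-acid Q3 fragment)
# reduce to sums over this table.

#' Monoisotopic atomic masses
#'
#' Returns the monoisotopic atomic mass table used by [monoisotopic_mass()].
#' Carbon is exactly 12 by definition of the unified atomic mass unit.
#'
#' @param path Optional path to a tab-separated table with columns
#'   `element` and `mass` to use instead of the built-in table.
#' @return Named numeric vector of monoisotopic masses in Da.
#' @export
atomic_masses <- function(path = NULL) {
  if (is.null(path)) {
    return(c(
      C = 12,
      H = 1.00782503,
      N = 14.00307401,
      O = 15.99491462,
      S = 31.97207117,
      P = 30.97376199
    ))
  }
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("element", "mass") %in% names(tbl))) {
    stop("atomic mass table needs columns 'element' and 'mass'")
  }
  stats::setNames(as.numeric(tbl$mass), tbl$element)
}

#' Mass of the proton, in Da
#'
#' Used for deprotonation arithmetic in negative-mode m/z calculation.
#' The electron mass (0.00055 Da) is neglected; the difference is invisible
#' at one-decimal m/z reporting.
#' @export
proton_mass <- function() 1.00727646

#' Create an elemental composition
#'
#' An elemental composition is a named integer vector of non-negative atom
#' counts (class `element_composition`). Compositions add element-wise and
#' their monoisotopic masses are additive.
#'
#' @param formula A molecular formula string such as `"C6H10O5"`. Element
#'   symbols are one capital letter optionally followed by a lowercase
#'   letter; a missing count means 1.
#' @param counts Alternatively, a named numeric vector of atom counts.
#' @return An `element_composition` object.
#' @examples
#' composition("C6H10O5")
#' composition(counts = c(C = 6, H = 12, O = 6))
#' @export
composition <- function(formula = NULL, counts = NULL) {
  if (!is.null(formula)) {
    stopifnot(is.character(formula), length(formula) == 1)
    if (formula == "") {
      counts <- stats::setNames(numeric(0), character(0))
    } else {
      m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
      parts <- regmatches(formula, list(m))[[1]]
      if (sum(nchar(parts)) != nchar(formula)) {
        stop("cannot parse formula: ", formula)
      }
      elems <- sub("[0-9]*$", "", parts)
      nums <- sub("^[A-Z][a-z]?", "", parts)
      nums <- ifelse(nums == "", 1L, as.integer(nums))
      counts <- tapply(nums, elems, sum)
      counts <- stats::setNames(as.numeric(counts), names(counts))
    }
  }
  if (is.null(counts)) counts <- stats::setNames(numeric(0), character(0))
  if (length(counts) && (is.null(names(counts)) || any(names(counts) == ""))) {
    stop("composition counts must be named by element symbol")
  }
  if (any(counts < 0)) {
    stop("negative atom count for element(s): ",
         paste(names(counts)[counts < 0], collapse = ", "))
  }
  if (any(counts != round(counts))) stop("atom counts must be integers")
  counts <- counts[counts > 0]
  counts <- counts[order(names(counts))]
  structure(counts, class = "element_composition")
}

#' @export
print.element_composition <- function(x, ...) {
  cat("<composition>", format_composition(x), "\n")
  invisible(x)
}

#' Format a composition as a formula string
#' @param x An `element_composition`.
#' @return A character scalar, Hill-ish order (C, H, then alphabetical).
#' @export
format_composition <- function(x) {
  if (length(x) == 0) return("(empty)")
  elems <- names(x)
  ord <- order(match(elems, c("C", "H"), nomatch = 3L), elems)
  paste0(elems[ord], ifelse(unclass(x)[ord] == 1, "", unclass(x)[ord]),
         collapse = "")
}

#' Add two elemental compositions
#'
#' Element-wise sum; commutative and associative. The empty composition is
#' the identity.
#'
#' @param a,b `element_composition` objects.
#' @return Their element-wise sum.
#' @export
comp_add <- function(a, b) {
  stopifnot(inherits(a, "element_composition"),
            inherits(b, "element_composition"))
  elems <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(elems)), elems)
  out[names(a)] <- out[names(a)] + unclass(a)
  out[names(b)] <- out[names(b)] + unclass(b)
  composition(counts = out)
}

#' Subtract one elemental composition from another
#'
#' @param a,b `element_composition` objects.
#' @return `a - b`, element-wise. A negative resulting count is an error.
#' @export
comp_subtract <- function(a, b) {
  stopifnot(inherits(a, "element_composition"),
            inherits(b, "element_composition"))
  elems <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(elems)), elems)
  out[names(a)] <- out[names(a)] + unclass(a)
  out[names(b)] <- out[names(b)] - unclass(b)
  if (any(out < 0)) {
    stop("composition subtraction yields negative count for: ",
         paste(elems[out < 0], collapse = ", "))
  }
  composition(counts = out)
}

#' @export
`+.element_composition` <- function(e1, e2) comp_add(e1, e2)

#' @export
`-.element_composition` <- function(e1, e2) comp_subtract(e1, e2)

#' Monoisotopic mass of a composition
#'
#' Sum of atom count times monoisotopic atomic mass. Additive:
#' `monoisotopic_mass(a + b) == monoisotopic_mass(a) + monoisotopic_mass(b)`
#' to well below 1e-9 Da.
#'
#' @param x An `element_composition` (or a formula string, converted).
#' @param masses Atomic mass table, defaults to [atomic_masses()].
#' @return Mass in Da; 0 for the empty composition.
#' @examples
#' monoisotopic_mass("C6H10O5")   # hexose residue, 162.0528
#' @export
monoisotopic_mass <- function(x, masses = atomic_masses()) {
  if (is.character(x)) x <- composition(x)
  stopifnot(inherits(x, "element_composition"))
  if (length(x) == 0) return(0)
  unknown <- setdiff(names(x), names(masses))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(unclass(x) * masses[names(x)])
}

# --- building blocks ------------------------------------------------------

# Dehydro (residue) compositions: the mass added per glycosidic attachment,
# i.e. the free monosaccharide minus one water. Glc/Gal collapse to Hex and
# GlcNAc/GalNAc to HexNAc, which are mass-degenerate.
.RESIDUE_FORMULAS <- c(
  Hex    = "C6H10O5",
  HexNAc = "C8H13NO5",
  NeuAc  = "C11H17NO8",
  dHex   = "C6H10O4"
)

#' Monosaccharide residue composition
#'
#' Residue (dehydrated) compositions of the four monosaccharide classes that
#' make up acidic glycosphingolipid headgroups: Hex (Glc/Gal), HexNAc
#' (GlcNAc/GalNAc), NeuAc (sialic acid) and dHex (fucose).
#'
#' @param name One of `"Hex"`, `"HexNAc"`, `"NeuAc"`, `"dHex"`.
#' @return An `element_composition`.
#' @export
residue_composition <- function(name) {
  f <- .RESIDUE_FORMULAS[name]
  if (is.na(f)) {
    stop("unknown monosaccharide residue: ", name,
         " (known: ", paste(names(.RESIDUE_FORMULAS), collapse = ", "), ")")
  }
  composition(unname(f))
}

#' Sphingoid base composition
#'
#' Free-base composition of a dihydroxy sphingoid base `dC:D`
#' (C carbons, D double bonds): `C_c H_(2c+3-2d) N O2`. The default base
#' throughout the package is sphingosine, d18:1 (C18H37NO2).
#'
#' @param shorthand e.g. `"d18:1"`.
#' @return List with `shorthand` and `composition`, class `sphingoid_base`.
#' @export
sphingoid_base <- function(shorthand = "d18:1") {
  m <- regmatches(shorthand, regexec("^d([0-9]+):([0-9]+)$", shorthand))[[1]]
  if (length(m) != 3) {
    stop("cannot parse sphingoid base shorthand: ", shorthand,
         " (expected like 'd18:1')")
  }
  c_n <- as.integer(m[2]); d_n <- as.integer(m[3])
  comp <- composition(counts = c(C = c_n, H = 2 * c_n + 3 - 2 * d_n,
                                 N = 1, O = 2))
  structure(list(shorthand = shorthand, composition = comp),
            class = "sphingoid_base")
}

#' Fatty acyl chain
#'
#' A fatty acyl chain `c:d` with free-acid composition `C_c H_(2c-2d) O2`.
#' Chains outside 14-30 carbons or with more double bonds than c/2 are
#' rejected: that is the chemically meaningful range for glycosphingolipid
#' N-acyl chains covered here.
#'
#' @param carbons Chain length (14-30).
#' @param double_bonds Number of C=C double bonds.
#' @return List with `carbons`, `double_bonds`, `shorthand`, `composition`
#'   (free fatty acid), class `fatty_acyl`.
#' @export
fatty_acyl <- function(carbons, double_bonds = 0) {
  carbons <- as.integer(carbons); double_bonds <- as.integer(double_bonds)
  if (carbons < 14 || carbons > 30) {
    stop("fatty acyl carbons must be in 14..30, got ", carbons)
  }
  if (double_bonds < 0 || double_bonds > carbons / 2) {
    stop("fatty acyl double bonds must be in 0..carbons/2, got ", double_bonds)
  }
  comp <- composition(counts = c(C = carbons,
                                 H = 2 * carbons - 2 * double_bonds, O = 2))
  structure(list(carbons = carbons, double_bonds = double_bonds,
                 shorthand = paste0(carbons, ":", double_bonds),
                 composition = comp),
            class = "fatty_acyl")
}

#' Parse a fatty acyl shorthand like "16:0"
#' @param shorthand Character scalar `"c:d"`.
#' @return A `fatty_acyl`.
#' @export
parse_fatty_acyl <- function(shorthand) {
  m <- regmatches(shorthand, regexec("^([0-9]+):([0-9]+)$", shorthand))[[1]]
  if (length(m) != 3) stop("cannot parse fatty acyl shorthand: ", shorthand)
  fatty_acyl(as.integer(m[2]), as.integer(m[3]))
}

#' Ceramide from sphingoid base and fatty acyl
#'
#' Amide condensation: composition = base + free fatty acid - H2O.
#' d18:1/16:0 is C34H67NO3.
#'
#' @param base A `sphingoid_base` (or shorthand string).
#' @param acyl A `fatty_acyl` (or shorthand string).
#' @return List with `base`, `acyl`, `shorthand`, `composition`,
#'   class `ceramide`.
#' @export
ceramide <- function(base = "d18:1", acyl) {
  if (is.character(base)) base <- sphingoid_base(base)
  if (is.character(acyl)) acyl <- parse_fatty_acyl(acyl)
  stopifnot(inherits(base, "sphingoid_base"), inherits(acyl, "fatty_acyl"))
  comp <- comp_subtract(comp_add(base$composition, acyl$composition),
                        composition("H2O"))
  structure(list(base = base, acyl = acyl,
                 shorthand = paste0(base$shorthand, "/", acyl$shorthand),
                 composition = comp),
            class = "ceramide")
}

#' Glycan headgroup
#'
#' An acidic glycosphingolipid headgroup defined by residue counts. Every
#' catalog entry must carry at least one NeuAc (the method targets acidic
#' GSLs and monitors the sialic-acid fragment). Composition is the sum of
#' residue compositions; residues are pre-dehydrated so attaching the
#' headgroup to a ceramide needs no further water correction.
#'
#' @param name Display label, e.g. `"DSGb5"`.
#' @param hex,hexnac,neuac,dhex Residue counts.
#' @param series One of `"globo"`, `"ganglio"`, `"lacto"` (annotation only).
#' @param note Free-text annotation (e.g. provenance of the residue counts).
#' @return List with the counts, `series`, `composition`, class
#'   `glycan_headgroup`.
#' @export
glycan_headgroup <- function(name, hex = 0, hexnac = 0, neuac = 1, dhex = 0,
                             series = NA_character_, note = "") {
  counts <- c(hex = hex, hexnac = hexnac, neuac = neuac, dhex = dhex)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("residue counts must be non-negative integers")
  }
  if (neuac < 1) {
    stop("glycan '", name, "' has no NeuAc; only acidic glycans are in scope")
  }
  comp <- composition("")
  for (r in c("Hex", "HexNAc", "NeuAc", "dHex")) {
    n <- counts[tolower(r)]
    if (r == "dHex") n <- counts["dhex"]
    if (n > 0) {
      for (i in seq_len(n)) comp <- comp_add(comp, residue_composition(r))
    }
  }
  structure(list(name = name, hex = as.integer(hex),
                 hexnac = as.integer(hexnac), neuac = as.integer(neuac),
                 dhex = as.integer(dhex), series = series, note = note,
                 composition = comp),
            class = "glycan_headgroup")
}

#' Glycosphingolipid species
#'
#' A glycan headgroup attached to a ceramide. The neutral composition is the
#' plain sum of the two parts.
#'
#' @param glycan A `glycan_headgroup`.
#' @param cer A `ceramide`.
#' @return List with `glycan`, `ceramide`, `name` (`"Glycan (base/acyl)"`),
#'   `composition`, class `gsl_species`.
#' @export
gsl_species <- function(glycan, cer) {
  stopifnot(inherits(glycan, "glycan_headgroup"), inherits(cer, "ceramide"))
  structure(list(glycan = glycan, ceramide = cer,
                 name = paste0(glycan$name, " (", cer$shorthand, ")"),
                 composition = comp_add(glycan$composition, cer$composition)),
            class = "gsl_species")
}

#' Neutral monoisotopic mass of a GSL species
#' @param s A `gsl_species`.
#' @return Mass in Da.
#' @export
neutral_mass <- function(s) {
  stopifnot(inherits(s, "gsl_species"))
  monoisotopic_mass(s$composition)
}

#' m/z of a deprotonated ion
#'
#' `[M - zH]^z-` precursor m/z: `(neutral - z * proton) / z`. The electron
#' mass is neglected (invisible at one-decimal reporting).
#'
#' @param neutral Neutral monoisotopic mass in Da.
#' @param z Charge (number of protons removed), a positive integer.
#' @return m/z, unrounded. Use [round_mz()] for the one-decimal reporting
#'   convention.
#' @export
mz_deprotonated <- function(neutral, z) {
  if (any(z < 1) || any(z != round(z))) {
    stop("charge z must be a positive integer")
  }
  if (any(neutral <= z * proton_mass())) {
    stop("neutral mass must exceed the mass of the removed protons")
  }
  (neutral - z * proton_mass()) / z
}

#' Sialic-acid product-ion m/z
#'
#' The deprotonated NeuAc residue anion used as Q3 for every transition:
#' monoisotopic mass of C11H17NO8 minus a proton, 290.0881 (nominal 290).
#' It is independent of the precursor species.
#'
#' @param nominal If `TRUE`, return the nearest-integer nominal value (290).
#' @return m/z.
#' @export
neuac_fragment_mz <- function(nominal = FALSE) {
  mz <- monoisotopic_mass(residue_composition("NeuAc")) - proton_mass()
  if (nominal) nominal_mz(mz) else mz
}

#' Round m/z to the one-decimal reporting convention
#' @param x m/z values.
#' @return Values rounded to one decimal place.
#' @export
round_mz <- function(x) round(x, 1)

#' Nominal (integer) m/z
#'
#' Unit-resolution value as printed in spectra: the one-decimal m/z rounded
#' half-up to the nearest integer (so 917.5 reports as 918).
#' @param x m/z values.
#' @return Integer-valued numeric.
#' @export
nominal_mz <- function(x) floor(round(x, 1) + 0.5)
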