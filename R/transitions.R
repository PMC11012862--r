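# Enumeration of the wide-targeted species grid and SRM transition-list
# construction. One transition per (glycan, acyl) pair: Q1 is the
# deprotonated precursor with charge set by the NeuAc count, Q3 is the
# common sialic-acid fragment, CE is looked up by NeuAc count.

.read_tsv <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                           check.names = FALSE)
  for (j in seq_along(tbl)) if (is.character(tbl[[j]])) {
    tbl[[j]][is.na(tbl[[j]])] <- ""
  }
  tbl
}

#' Read a glycan catalog from a delimited text file
#'
#' Expected tab-separated columns: `name`, `hex`, `hexnac`, `neuac`, `dhex`,
#' and optionally `series` and `note`.
#'
#' @param path File path.
#' @return A list of `glycan_headgroup` objects, in file order.
#' @export
read_glycan_catalog <- function(path) {
  tbl <- .read_tsv(path)
  need <- c("name", "hex", "hexnac", "neuac", "dhex")
  if (!all(need %in% names(tbl))) {
    stop("glycan catalog needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tbl$name)) {
    stop("duplicate glycan names in catalog: ",
         paste(unique(tbl$name[duplicated(tbl$name)]), collapse = ", "))
  }
  lapply(seq_len(nrow(tbl)), function(i) {
    glycan_headgroup(tbl$name[i], tbl$hex[i], tbl$hexnac[i], tbl$neuac[i],
                     tbl$dhex[i],
                     series = if ("series" %in% names(tbl)) tbl$series[i]
                              else NA_character_,
                     note = if ("note" %in% names(tbl)) tbl$note[i] else "")
  })
}

#' Default 10-glycan acidic-GSL catalog
#'
#' GM3, GM2, GM1, GD1a (ganglio), MSGb5, DSGb5 (globo), DSLc4, GalNAcDSLc4,
#' DUPAN-2, CA19-9 (lacto). Residue counts follow the standard antigen
#' definitions; DUPAN-2 and CA19-9 are flagged as assumptions in the
#' shipped catalog file. Three mass-isomeric pairs exist by construction
#' (GD1a/DSLc4, GM1/DUPAN-2) and are kept as distinct analytes because LC
#' retention resolves them.
#'
#' @return A list of `glycan_headgroup` objects.
#' @export
default_glycan_catalog <- function() {
  read_glycan_catalog(system.file("extdata", "glycan_catalog.tsv",
                                  package = "gslsrm", mustWork = TRUE))
}

#' Default 24-chain fatty-acyl list
#'
#' A reconstruction spanning C14-C30: all even saturated chains 14:0-30:0,
#' odd saturated 15:0-29:0, and monounsaturated 16:1-28:1 (even chains).
#' The published per-method chain list is not available, so this list
#' preserves the published count (24) and carbon range (14-30) and is fully
#' overridable via [transition_config()].
#'
#' @return A list of `fatty_acyl` objects.
#' @export
default_acyl_chains <- function() {
  tbl <- .read_tsv(system.file("extdata", "acyl_chains.tsv",
                               package = "gslsrm", mustWork = TRUE))
  lapply(tbl$shorthand, parse_fatty_acyl)
}

#' Default collision-energy lookup by NeuAc count
#'
#' CE varies with the NeuAc count because the count sets the precursor
#' charge state. The published optimized values are not available; these are
#' placeholder magnitudes (volts) in the range typical for negative-mode
#' glycolipid SRM, overridable via [transition_config()].
#'
#' @return Named numeric vector, names = NeuAc count.
#' @export
default_ce_table <- function() {
  tbl <- .read_tsv(system.file("extdata", "ce_table.tsv",
                               package = "gslsrm", mustWork = TRUE))
  stats::setNames(as.numeric(tbl$ce), as.character(tbl$neuac))
}

#' Build a transition-list configuration
#'
#' Bundles everything [build_transitions()] needs: the glycan catalog, the
#' fatty-acyl list, the sphingoid base, the CE lookup, the common Q3, source
#' parameters and the retention-time window.
#'
#' @param glycans List of `glycan_headgroup` (default: the 10-entry catalog).
#' @param acyls List of `fatty_acyl` (default: the 24-chain list).
#' @param base Sphingoid base (default d18:1, the only base the method uses).
#' @param ce_table Named numeric vector mapping NeuAc count to CE (volts).
#' @param q3_mz Common product-ion m/z (default: sialic-acid fragment,
#'   290.09 at two decimals).
#' @param dp Declustering potential placeholder (volts).
#' @param cxp Cell exit potential placeholder (volts).
#' @param rt_window Retention-time window `c(start, stop)` in minutes;
#'   defaults to the full 0-45 min gradient since per-analyte retention
#'   times are not published.
#' @return A `transition_config` object (validated).
#' @export
transition_config <- function(glycans = default_glycan_catalog(),
                              acyls = default_acyl_chains(),
                              base = sphingoid_base("d18:1"),
                              ce_table = default_ce_table(),
                              q3_mz = round(neuac_fragment_mz(), 2),
                              dp = 100, cxp = 15,
                              rt_window = c(0, 45)) {
  if (is.character(base)) base <- sphingoid_base(base)
  cfg <- structure(list(glycans = glycans, acyls = acyls, base = base,
                        ce_table = ce_table, q3_mz = q3_mz, dp = dp,
                        cxp = cxp, rt_window = rt_window),
                   class = "transition_config")
  validate_transition_config(cfg)
  cfg
}

#' Validate a transition configuration
#'
#' Checks: non-empty glycan catalog with unique names and NeuAc >= 1
#' everywhere; non-empty acyl list with unique shorthands; CE table covering
#' every NeuAc count present; sane Q3 and RT window.
#'
#' @param cfg A `transition_config`.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_transition_config <- function(cfg) {
  stopifnot(inherits(cfg, "transition_config"))
  if (length(cfg$glycans) == 0) stop("glycan catalog is empty")
  if (length(cfg$acyls) == 0) stop("acyl list is empty")
  gnames <- vapply(cfg$glycans, `[[`, "", "name")
  if (anyDuplicated(gnames)) {
    stop("duplicate glycan names: ",
         paste(unique(gnames[duplicated(gnames)]), collapse = ", "))
  }
  anames <- vapply(cfg$acyls, `[[`, "", "shorthand")
  if (anyDuplicated(anames)) {
    stop("duplicate acyl shorthands: ",
         paste(unique(anames[duplicated(anames)]), collapse = ", "))
  }
  neuacs <- vapply(cfg$glycans, `[[`, 0L, "neuac")
  if (any(neuacs < 1)) stop("catalog contains a glycan without NeuAc")
  missing_ce <- setdiff(as.character(unique(neuacs)), names(cfg$ce_table))
  if (length(missing_ce)) {
    stop("ce_table missing entries for NeuAc count(s): ",
         paste(missing_ce, collapse = ", "))
  }
  if (!is.numeric(cfg$q3_mz) || cfg$q3_mz <= 0) stop("q3_mz must be positive")
  if (length(cfg$rt_window) != 2 || cfg$rt_window[1] >= cfg$rt_window[2]) {
    stop("rt_window must be c(start, stop) with start < stop")
  }
  invisible(cfg)
}

#' Read a transition configuration from a JSON file
#'
#' Fields (all optional, defaults apply): `glycans` (array of objects with
#' name/hex/hexnac/neuac/dhex/series), `acyls` (array of `"c:d"` strings),
#' `base` (string), `ce_table` (object NeuAc count -> volts), `q3_mz`,
#' `dp`, `cxp`, `rt_window` (two numbers).
#'
#' @param path JSON file path.
#' @return A validated `transition_config`.
#' @export
read_transition_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  glycans <- if (!is.null(j$glycans)) {
    g <- j$glycans
    lapply(seq_len(nrow(g)), function(i) {
      glycan_headgroup(g$name[i], g$hex[i], g$hexnac[i], g$neuac[i],
                       if ("dhex" %in% names(g)) g$dhex[i] else 0,
                       series = if ("series" %in% names(g)) g$series[i]
                                else NA_character_)
    })
  } else default_glycan_catalog()
  acyls <- if (!is.null(j$acyls)) lapply(j$acyls, parse_fatty_acyl)
           else default_acyl_chains()
  ce <- if (!is.null(j$ce_table)) unlist(j$ce_table) else default_ce_table()
  transition_config(
    glycans = glycans, acyls = acyls,
    base = if (!is.null(j$base)) j$base else sphingoid_base("d18:1"),
    ce_table = ce,
    q3_mz = if (!is.null(j$q3_mz)) j$q3_mz else round(neuac_fragment_mz(), 2),
    dp = if (!is.null(j$dp)) j$dp else 100,
    cxp = if (!is.null(j$cxp)) j$cxp else 15,
    rt_window = if (!is.null(j$rt_window)) as.numeric(j$rt_window)
                else c(0, 45))
}

#' Enumerate the species grid
#'
#' Cartesian product of catalog glycans and acyl chains on the configured
#' sphingoid base, in deterministic order: catalog order major, acyl order
#' minor. With the defaults this is 10 x 24 = 240 species.
#'
#' @param cfg A `transition_config`.
#' @return A list of `gsl_species`, length `|glycans| * |acyls|`.
#' @export
enumerate_species <- function(cfg) {
  validate_transition_config(cfg)
  out <- vector("list", length(cfg$glycans) * length(cfg$acyls))
  k <- 1L
  for (g in cfg$glycans) {
    for (a in cfg$acyls) {
      out[[k]] <- gsl_species(g, ceramide(cfg$base, a))
      k <- k + 1L
    }
  }
  out
}

#' Precursor charge state from the NeuAc count
#'
#' Acidic GSLs deprotonate on their sialic acids: species with two or more
#' NeuAc are monitored as `[M-2H]^2-`, mono-sialylated species as `[M-H]^-`.
#'
#' @param s A `gsl_species`, or a NeuAc count.
#' @return Charge, 1 or 2.
#' @export
assign_charge <- function(s) {
  n <- if (inherits(s, "gsl_species")) s$glycan$neuac else as.integer(s)
  if (any(n < 1)) stop("NeuAc count must be >= 1 (acidic GSLs only)")
  ifelse(n >= 2, 2L, 1L)
}

# shared label for catalog glycans with identical residue counts
.isomer_groups <- function(glycans) {
  key <- vapply(glycans, function(g) {
    paste0("Hex", g$hex, "HexNAc", g$hexnac, "NeuAc", g$neuac,
           if (g$dhex > 0) paste0("dHex", g$dhex) else "")
  }, "")
  dupkeys <- unique(key[duplicated(key)])
  ifelse(key %in% dupkeys, key, "")
}

#' Build the SRM transition list
#'
#' One transition per enumerated species. Q1 is the deprotonated precursor
#' m/z rounded to one decimal (the reporting convention); Q3 is the common
#' sialic-acid fragment; CE comes from the NeuAc-count lookup; DP/CXP and
#' the retention-time window are copied from the config. Glycans with
#' identical residue counts share an `isomer_group` label and deliberately
#' produce duplicate (Q1, Q3) pairs -- LC retention separates them.
#'
#' @param cfg A `transition_config`.
#' @return A data.frame of class `srm_transitions` with columns `id`, `q1`,
#'   `q1_exact`, `q3`, `charge`, `ce`, `dp`, `cxp`, `rt_start`, `rt_stop`,
#'   `isomer_group`.
#' @examples
#' ts <- build_transitions(transition_config())
#' nrow(ts)   # 240
#' @export
build_transitions <- function(cfg) {
  validate_transition_config(cfg)
  species <- enumerate_species(cfg)
  iso <- rep(.isomer_groups(cfg$glycans), each = length(cfg$acyls))
  n <- length(species)
  q1e <- numeric(n); z <- integer(n); ce <- numeric(n); id <- character(n)
  for (k in seq_len(n)) {
    s <- species[[k]]
    z[k] <- assign_charge(s)
    q1e[k] <- mz_deprotonated(neutral_mass(s), z[k])
    ce[k] <- cfg$ce_table[[as.character(s$glycan$neuac)]]
    id[k] <- s$name
  }
  structure(data.frame(
    id = id, q1 = round_mz(q1e), q1_exact = q1e, q3 = cfg$q3_mz,
    charge = z, ce = ce, dp = cfg$dp, cxp = cfg$cxp,
    rt_start = cfg$rt_window[1], rt_stop = cfg$rt_window[2],
    isomer_group = iso, stringsAsFactors = FALSE),
    class = c("srm_transitions", "data.frame"))
}

#' Export a transition list as delimited text
#'
#' Vendor-neutral tab-separated table importable into acquisition software.
#' The `generic` dialect writes columns id, Q1, Q3, RT_window_start,
#' RT_window_stop, DP, CE, CXP, charge, isomer_group; it round-trips
#' losslessly through [read_transition_list()] (Q1 is the one-decimal
#' reported value; the exact value is recomputable from the config).
#'
#' @param ts An `srm_transitions` data.frame.
#' @param path Output file path.
#' @param dialect Currently only `"generic"`.
#' @return `path`, invisibly.
#' @export
export_transition_list <- function(ts, path, dialect = "generic") {
  stopifnot(inherits(ts, "srm_transitions"), nrow(ts) > 0)
  dialect <- match.arg(dialect, "generic")
  out <- data.frame(id = ts$id, Q1 = ts$q1, Q3 = ts$q3,
                    RT_window_start = ts$rt_start,
                    RT_window_stop = ts$rt_stop,
                    DP = ts$dp, CE = ts$ce, CXP = ts$cxp,
                    charge = ts$charge, isomer_group = ts$isomer_group,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transition list written by [export_transition_list()]
#' @param path File path.
#' @return An `srm_transitions` data.frame (with `q1_exact = q1`, since the
#'   text format carries the reported one-decimal value).
#' @export
read_transition_list <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  tbl$isomer_group[is.na(tbl$isomer_group)] <- ""
  structure(data.frame(
    id = tbl$id, q1 = tbl$Q1, q1_exact = tbl$Q1, q3 = tbl$Q3,
    charge = as.integer(tbl$charge), ce = tbl$CE, dp = tbl$DP,
    cxp = tbl$CXP, rt_start = tbl$RT_window_start,
    rt_stop = tbl$RT_window_stop, isomer_group = tbl$isomer_group,
    stringsAsFactors = FALSE),
    class = c("srm_transitions", "data.frame"))
}
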