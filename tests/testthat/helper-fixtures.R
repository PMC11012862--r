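# Shared fixtures built in code: a small glycan catalog, convenience
# accessors into the default catalog, and frozen atomic masses for
# independent hand computation of expected values.

# independent atomic masses (same physical constants, used to hand-compute
# expected values without going through composition())
AM <- c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462)
PROTON <- 1.00727646

# hand-summed residue and part masses (the independent oracle route)
hand_mass <- function(c = 0, h = 0, n = 0, o = 0) {
  c * AM["C"] + h * AM["H"] + n * AM["N"] + o * AM["O"]
}
M_HEX <- unname(hand_mass(6, 10, 0, 5))
M_HEXNAC <- unname(hand_mass(8, 13, 1, 5))
M_NEUAC <- unname(hand_mass(11, 17, 1, 8))
M_DHEX <- unname(hand_mass(6, 10, 0, 4))

catalog_glycan <- function(name) {
  cat0 <- default_glycan_catalog()
  idx <- which(vapply(cat0, `[[`, "", "name") == name)
  stopifnot(length(idx) == 1)
  cat0[[idx]]
}

default_q1 <- function(glycan_name, acyl) {
  s <- gsl_species(catalog_glycan(glycan_name), ceramide("d18:1", acyl))
  round_mz(mz_deprotonated(neutral_mass(s), assign_charge(s)))
}

small_config <- function(n_glycans = 3, n_acyls = 5) {
  transition_config(glycans = default_glycan_catalog()[seq_len(n_glycans)],
                    acyls = default_acyl_chains()[seq_len(n_acyls)])
}

random_composition <- function() {
  elems <- c("C", "H", "N", "O")
  composition(counts = stats::setNames(sample(0:40, 4, replace = TRUE),
                                       elems))
}
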