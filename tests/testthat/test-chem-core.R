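# Elemental compositions, monoisotopic masses, m/z arithmetic.

test_that("composition parsing and arithmetic behave as element-wise sums", {
  hex <- composition("C6H10O5")
  expect_equal(unclass(comp_add(hex, hex)),
               unclass(composition("C12H20O10")))
  # identity and commutativity
  expect_equal(unclass(comp_add(hex, composition(""))), unclass(hex))
  a <- composition("C8H13NO5"); b <- composition("C11H17NO8")
  expect_equal(unclass(comp_add(a, b)), unclass(comp_add(b, a)))
  # amide condensation by hand atom count: d18:1 base + 16:0 acid - H2O
  cer <- comp_subtract(comp_add(composition("C18H37NO2"),
                                composition("C16H32O2")),
                       composition("H2O"))
  expect_equal(format_composition(cer), "C34H67NO3")
  # negative counts are rejected
  expect_error(comp_subtract(composition("C2H4"), composition("C3H4")),
               "negative")
  expect_error(composition(counts = c(C = -1)), "negative")
})

test_that("monoisotopic masses match independent atomic-mass summation", {
  expect_equal(monoisotopic_mass("C6H10O5"), M_HEX, tolerance = 1e-12)
  expect_equal(round(M_HEX, 4), 162.0528)
  expect_equal(monoisotopic_mass(composition("")), 0)
  m_cer <- unname(hand_mass(34, 67, 1, 3))
  expect_equal(monoisotopic_mass("C34H67NO3"), m_cer, tolerance = 1e-12)
  expect_equal(round(m_cer, 4), 537.5121)
  expect_error(monoisotopic_mass(composition(counts = c(Xx = 1))), "Xx")
})

test_that("mass additivity holds on random composition pairs", {
  set.seed(42)
  for (i in 1:50) {
    a <- random_composition(); b <- random_composition()
    expect_equal(monoisotopic_mass(comp_add(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-12)
  }
})

test_that("building blocks have the stated compositions", {
  expect_equal(format_composition(residue_composition("Hex")), "C6H10O5")
  expect_equal(format_composition(residue_composition("HexNAc")), "C8H13NO5")
  expect_equal(format_composition(residue_composition("NeuAc")), "C11H17NO8")
  expect_equal(format_composition(residue_composition("dHex")), "C6H10O4")
  expect_error(residue_composition("Pent"), "Pent")
  expect_equal(format_composition(sphingoid_base("d18:1")$composition),
               "C18H37NO2")
  expect_equal(format_composition(ceramide("d18:1", "16:0")$composition),
               "C34H67NO3")
  # fatty acid free-acid composition C_c H_(2c-2d) O2
  expect_equal(format_composition(fatty_acyl(24, 1)$composition), "C24H46O2")
  expect_error(fatty_acyl(12, 0), "14")
  expect_error(fatty_acyl(31, 0), "30")
  expect_error(fatty_acyl(16, 9), "double bonds")
})

test_that("neutral masses of catalog species match the residue-sum oracle", {
  m_cer16 <- unname(hand_mass(34, 67, 1, 3))
  m_cer18 <- unname(hand_mass(36, 71, 1, 3))
  cases <- list(
    list(glycan = "DSGb5", residues = 4 * M_HEX + M_HEXNAC + 2 * M_NEUAC,
         cer = m_cer16, acyl = "16:0"),
    list(glycan = "GM3", residues = 2 * M_HEX + M_NEUAC,
         cer = m_cer16, acyl = "16:0"),
    list(glycan = "GD1a", residues = 3 * M_HEX + M_HEXNAC + 2 * M_NEUAC,
         cer = m_cer18, acyl = "18:0"))
  for (cs in cases) {
    s <- gsl_species(catalog_glycan(cs$glycan), ceramide("d18:1", cs$acyl))
    expect_equal(neutral_mass(s), cs$residues + cs$cer, tolerance = 1e-9)
  }
  # frozen oracle values
  s <- gsl_species(catalog_glycan("DSGb5"), ceramide("d18:1", "16:0"))
  expect_equal(neutral_mass(s), 1970.9936, tolerance = 1e-4)
  s <- gsl_species(catalog_glycan("GD1a"), ceramide("d18:1", "18:0"))
  expect_equal(neutral_mass(s), 1836.9721, tolerance = 1e-4)
})

test_that("deprotonated m/z follows (M - z*proton)/z and rounds to print", {
  neutral <- 1970.99359
  expect_equal(mz_deprotonated(neutral, 2),
               (neutral - 2 * PROTON) / 2, tolerance = 1e-12)
  expect_equal(round_mz(mz_deprotonated(neutral, 2)), 984.5)
  expect_error(mz_deprotonated(1000, 0), "positive integer")
  expect_error(mz_deprotonated(1000, -1), "positive integer")
  expect_error(mz_deprotonated(1.0, 2), "exceed")
})

test_that("sialic-acid fragment is the deprotonated NeuAc residue anion", {
  expect_equal(neuac_fragment_mz(), M_NEUAC - PROTON, tolerance = 1e-9)
  expect_equal(round(neuac_fragment_mz(), 2), 290.09)
  expect_equal(neuac_fragment_mz(nominal = TRUE), 290)
})

test_that("homolog ladder and unsaturation shifts are exact", {
  ch2 <- unname(hand_mass(1, 2))       # 14.01565
  h2 <- unname(hand_mass(0, 2))        # 2.01565
  g <- catalog_glycan("GM1")
  for (c_n in c(16, 18, 24)) {
    m0 <- neutral_mass(gsl_species(g, ceramide("d18:1", paste0(c_n, ":0"))))
    m1 <- neutral_mass(gsl_species(g, ceramide("d18:1",
                                               paste0(c_n + 1, ":0"))))
    expect_equal(m1 - m0, ch2, tolerance = 1e-9)
    mdb <- neutral_mass(gsl_species(g, ceramide("d18:1",
                                                paste0(c_n, ":1"))))
    expect_equal(m0 - mdb, h2, tolerance = 1e-9)
    # Q1 shifts by CH2/z along the ladder
    z <- assign_charge(gsl_species(g, ceramide("d18:1", paste0(c_n, ":0"))))
    expect_equal(mz_deprotonated(m1, z) - mz_deprotonated(m0, z), ch2 / z,
                 tolerance = 1e-9)
  }
})

test_that("isomeric glycans are mass-identical for every ceramide", {
  pairs <- list(c("GD1a", "DSLc4"), c("GM1", "DUPAN-2"))
  for (p in pairs) {
    for (ac in c("14:0", "18:1", "30:0")) {
      cer <- ceramide("d18:1", ac)
      expect_equal(neutral_mass(gsl_species(catalog_glycan(p[1]), cer)),
                   neutral_mass(gsl_species(catalog_glycan(p[2]), cer)),
                   tolerance = 1e-9)
    }
  }
})

test_that("glycan headgroups reject non-acidic entries", {
  expect_error(glycan_headgroup("LacCer", hex = 2, neuac = 0), "NeuAc")
})
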