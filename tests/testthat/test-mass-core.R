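# Monoisotopic mass arithmetic against published values and invariants.

test_that("neutral peptide masses reproduce published values at printed precision", {
  printed <- c(SRLPGP = 625.3547, TPILPQ = 667.3904, SSKAPPP = 682.3650,
               SLPSP = 499.2642, SKAPPPSLPSP = 1076.5866,
               SRLPGPSDTPILPQ = 1476.7936, SLPSPSRLPGP = 1106.6084,
               SSKAPPPSLP = 979.5338, SSKAPPPSLPSP = 1163.6186,
               SPSRLPGPSDTPILPQ = 1660.8784, SLPSPSRLPGPSDTPILPQ = 1958.0472)
  for (pep in names(printed))
    expect_lt(abs(peptide_mass(pep) - printed[[pep]]), 1.5e-4)
  expect_equal(peptide_mass("G"), 75.0320, tolerance = 1e-6)
})

test_that("peptide_mass validates input and applies variable mods", {
  expect_error(peptide_mass("SRXLP"), "position 3")
  expect_error(peptide_mass(""), "non-empty")
  expect_equal(peptide_mass("MSLP", data.frame(position = 1, mod = "oxidation")),
               peptide_mass("MSLP") + 15.995)
  expect_equal(peptide_mass("QSLP", data.frame(position = 1, mod = "deamidation")),
               peptide_mass("QSLP") + 0.9804)
  expect_error(peptide_mass("MS", data.frame(position = 5, mod = "oxidation")),
               "outside")
})

test_that("glycan masses: residue and free-reducing forms", {
  expect_equal(glycan_mass(core1, "residue"), 365.1322, tolerance = 1e-6)
  expect_equal(glycan_mass(core1, "free_reducing"), 383.1428, tolerance = 1e-6)
  expect_equal(glycan_mass(glycan_composition(HexNAc = 1)), 203.0794,
               tolerance = 1e-6)
  expect_error(glycan_composition(), "empty")
  expect_error(glycan_composition(HexNAc = -1), "non-negative")
})

test_that("2-AB labeled glycan m/z reproduces the published profile values", {
  mk <- function(comp, state = "intact")
    glycan_species(comp, label = "two_AB", state = state)
  expect_equal(round(labeled_glycan_mz(mk(core1)), 2), 504.22)
  # 795.32 is the *observed* peak; theory (795.3142) agrees within 0.02 Da
  expect_lt(abs(labeled_glycan_mz(mk(core1_neuac1)) - 795.32), 0.02)
  expect_equal(round(labeled_glycan_mz(mk(core1_neuac2)), 2), 1086.41)
  expect_equal(round(labeled_glycan_mz(mk(glycan_composition(Hex = 1, NeuAc = 1))), 2),
               592.23)
  expect_equal(round(labeled_glycan_mz(mk(glycan_composition(NeuAc = 1))), 2),
               430.18)
  # observed deacetylation byproducts printed as 753.31 / 1044.40; theory
  # matches within the 0.02 Da observed-value tolerance
  expect_lt(abs(labeled_glycan_mz(mk(core1_neuac1, "mono_deacetylated")) - 753.31),
            0.02)
  expect_lt(abs(labeled_glycan_mz(mk(core1_neuac2, "mono_deacetylated")) - 1044.40),
            0.02)
  expect_error(labeled_glycan_mz(mk(core1), charge = 0), "charge")
  expect_error(glycan_species(core1, state = "mono_deacetylated"), "NeuAc")
})

test_that("deacetylation shifts the labeled m/z by exactly acetyl/charge", {
  for (z in 1:3) {
    intact <- labeled_glycan_mz(glycan_species(core1_neuac2), z)
    deac <- labeled_glycan_mz(
      glycan_species(core1_neuac2, state = "mono_deacetylated"), z)
    expect_equal(intact - deac, 42.010565 / z, tolerance = 1e-9)
  }
})

test_that("glycopeptide precursor m/z matches derivation and observed values", {
  expect_equal(glycopeptide_mz("SRLPGP", list(`1` = core1), 1), 991.4940,
               tolerance = 1e-4)
  expect_lt(abs(glycopeptide_mz("SRLPGP", list(`1` = core1), 1) - 991.4922),
            0.02)  # observed value, ~2 ppm off theory
  expect_equal(glycopeptide_mz("SSKAPPP", list(`1` = core1, `2` = core1), 2),
               707.3220, tolerance = 1e-4)
  expect_equal(glycopeptide_mz("SLPSP"), peptide_mass("SLPSP") + 1.0072765)
  expect_error(glycopeptide_mz("SRLPGP", list(`2` = core1), 1), "non-S/T")
})

test_that("observed precursors of the reported glycopeptide inventory are within 10 ppm", {
  observed <- c("SKAPPPSLP|115" = 629.8241, "SLPSP|121" = 433.2047,
                "SRLPGPSDTPILPQ|126" = 921.9679, "SDTPILPQ|132" = 618.2975,
                "TPILPQ|134" = 517.2674, "SLPSPSRLPGP|121" = 736.8767,
                "SSKAPPP|114,115" = 707.3223, "SSKAPPPSLP|114,115" = 855.9053,
                "SSKAPPPSLP|114,121" = 855.9045,
                "SRLPGPSDTPILPQ|126,132" = 1104.5358,
                "SLPSPSRLPGPSDTPILPQ|121,132" = 897.1101,
                "SSKAPPPSLPSP|114,124" = 947.9465,
                "SSKAPPPSLPSP|114,115,121" = 754.0142,
                "SRLPGPSDTPILPQ|126,132,134" = 858.4017,
                "SPSRLPGPSDTPILPQ|124,126,132" = 919.7639)
  gps <- fsh_ctp_glycopeptides(TRUE)
  key <- vapply(gps, function(g)
    paste0(g$sequence, "|", paste(names(g$site_glycans), collapse = ",")),
    character(1))
  for (k in names(observed)) {
    gp <- gps[[match(k, key)]]
    theo <- gp_precursor_mz(gp, attr(gp, "charge"))
    expect_lt(abs(ppm_error(observed[[k]], theo)), 10)
  }
})

test_that("mass additivity: concatenation loses one water", {
  set.seed(11)
  aa <- names(mass_table()$residues)
  for (i in 1:20) {
    a <- paste(sample(aa, sample(1:12, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(1:12, 1), TRUE), collapse = "")
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("charge consistency: neutral mass recovered from any charge state", {
  p <- mass_table()$constants[["proton"]]
  for (z in 1:4) {
    mz <- glycopeptide_mz("SSKAPPP", list(`1` = core1, `2` = core1), z)
    expect_equal(mz * z - z * p,
                 peptide_mass("SSKAPPP") + 2 * glycan_mass(core1),
                 tolerance = 1e-6)
  }
})

test_that("ppm_error is the signed relative error in ppm", {
  expect_equal(ppm_error(500, 500), 0)
  expect_equal(ppm_error(500.005, 500), 10, tolerance = 1e-9)
  expect_equal(ppm_error(991.4922, 991.4940), -1.8, tolerance = 0.02)
  expect_error(ppm_error(500, 0), "theoretical")
})
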