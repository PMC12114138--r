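# Evidence-tier site localization and aggregation.

loc <- function(gp, spec, mode = "EThcD", enzyme_rule = TRUE,
                tolerance_ppm = 20) {
  matches <- match_peaks(spec, theoretical_ions(gp, mode = mode),
                         tolerance_ppm = tolerance_ppm)
  localize_spectrum(gp, matches, mode = mode, enzyme_rule = enzyme_rule,
                    spectrum_id = spec$id)
}

test_that("HCD single-candidate criterion: TPILPQ y5 localizes T134", {
  gp <- make_gp("TPILPQ", 134, 134)
  y5 <- backbone_ion_mz(gp, "y", 5)
  sp <- spectrum(gp_precursor_mz(gp, 1), 1,
                 data.frame(mz = y5, intensity = 100), "hcd_tpilpq")
  a <- loc(gp, sp, mode = "HCD")
  expect_equal(a$protein_position, 134L)
  expect_equal(a$evidence, "single_candidate")
  expect_equal(a$residue, "T")
})

test_that("HCD remnant criterion: SLPSP b2+N localizes S121", {
  gp <- make_gp("SLPSP", 121, 121)
  b2n <- backbone_ion_mz(gp, "b", 2, glycan_state = "hexnac_remnant")
  sp <- spectrum(gp_precursor_mz(gp, 1), 1,
                 data.frame(mz = b2n, intensity = 100), "hcd_slpsp")
  a <- loc(gp, sp, mode = "HCD")
  expect_equal(a$evidence[a$protein_position == 121], "remnant_localized")
})

test_that("naked HCD ions never localize in a multi-site peptide", {
  # glycan loss in HCD means a naked fragment cannot prove glycan location
  gp <- make_gp("SLPSP", 121, 121)  # SLPSP has two S/T (121, 124)
  b2 <- backbone_ion_mz(gp, "b", 2)  # naked, covers only S121
  sp <- spectrum(gp_precursor_mz(gp, 1), 1,
                 data.frame(mz = b2, intensity = 100), "hcd_naked")
  a <- loc(gp, sp, mode = "HCD")
  expect_equal(a$evidence, "enzyme_inferred")
  a2 <- loc(gp, sp, mode = "HCD", enzyme_rule = FALSE)
  expect_equal(a2$evidence, "ambiguous")
})

test_that("enzyme inference applies only to the N-terminal site", {
  gp <- make_gp("SSKAPPP", 114, c(114, 115))
  sp <- spectrum(gp_precursor_mz(gp, 2), 2,
                 data.frame(mz = 150, intensity = 1), "hcd_sskappp")
  a <- loc(gp, sp, mode = "HCD")
  expect_equal(a$evidence[a$protein_position == 114], "enzyme_inferred")
  expect_equal(a$evidence[a$protein_position == 115], "ambiguous")
  # with zero matches and the rule off, everything is ambiguous
  a2 <- loc(gp, sp, mode = "HCD", enzyme_rule = FALSE)
  expect_true(all(a2$evidence == "ambiguous"))
})

test_that("EThcD bracketing: SDTPILPQ z6 localizes S132", {
  gp <- make_gp("SDTPILPQ", 132, 132)
  z6 <- backbone_ion_mz(gp, "z_dot", 6)  # covers TPILPQ, glycan-free
  sp <- spectrum(gp_precursor_mz(gp, 2), 2,
                 data.frame(mz = z6, intensity = 100), "eth_sdtpilpq")
  a <- loc(gp, sp)
  expect_equal(a$evidence[a$protein_position == 132], "direct_bracketing")
})

test_that("EThcD: glycosylated SSKAPPP z6 localizes S114 and S115 at once", {
  gp <- make_gp("SSKAPPP", 114, c(114, 115))
  z6 <- backbone_ion_mz(gp, "z_dot", 6, glycan_state = "full")
  sp <- spectrum(gp_precursor_mz(gp, 2), 2,
                 data.frame(mz = z6, intensity = 100), "eth_sskappp")
  a <- loc(gp, sp)
  expect_equal(a$evidence[a$protein_position == 114], "direct_bracketing")
  expect_equal(a$evidence[a$protein_position == 115], "direct_bracketing")
})

test_that("noiseless full ladders recover every planted site by bracketing", {
  for (gp in fsh_ctp_glycopeptides(TRUE)) {
    sp <- perfect_spectrum(gp, charge = attr(gp, "charge"))
    a <- loc(gp, sp)
    expect_equal(sort(a$protein_position),
                 as.integer(names(gp$site_glycans)))
    expect_true(all(a$evidence == "direct_bracketing"), info = format(gp))
  }
})

test_that("aggregation keeps the best tier, counts peptides, flags novelty", {
  gp1 <- make_gp("SDTPILPQ", 132, 132)
  gp2 <- make_gp("SRLPGPSDTPILPQ", 126, c(126, 132))
  a1 <- loc(gp1, perfect_spectrum(gp1, id = "sp1"))
  # same site, weaker evidence from a matchless spectrum
  empty <- spectrum(gp_precursor_mz(gp2, 2), 2,
                    data.frame(mz = 150, intensity = 1), "sp2")
  a2 <- loc(gp2, empty)
  tab <- aggregate_sites(rbind(a1, a2), prior_sites = c(126, 132))
  expect_equal(tab$position, c(126L, 132L))
  expect_equal(tab$evidence[tab$position == 132], "direct_bracketing")
  expect_equal(tab$n_glycopeptides[tab$position == 132], 2L)
  expect_false(any(tab$novel))
  # aggregation is order-independent
  tab2 <- aggregate_sites(rbind(a2, a1), prior_sites = c(126, 132))
  expect_equal(tab, tab2)
  # novelty against the six prior sites
  gp3 <- make_gp("SPSRLPGPSDTPILPQ", 124, c(124, 126, 132))
  a3 <- loc(gp3, perfect_spectrum(gp3, id = "sp3"))
  tab3 <- aggregate_sites(rbind(a1, a2, a3), prior_sites = ctp$prior_sites)
  expect_true(tab3$novel[tab3$position == 124])
  expect_equal(sum(tab3$novel), 1L)
  # empty input -> empty table
  expect_equal(nrow(aggregate_sites(NULL)), 0)
})

test_that("evidence tiers are totally ordered and idempotent under merge", {
  lev <- evidence_levels()
  expect_equal(lev[1], "direct_bracketing")
  expect_equal(lev[length(lev)], "ambiguous")
  gp <- make_gp("SDTPILPQ", 132, 132)
  a <- loc(gp, perfect_spectrum(gp, id = "sp"))
  expect_equal(aggregate_sites(rbind(a, a), 132),
               aggregate_sites(a, 132))
})

test_that("localize_spectrum rejects mismatched inputs", {
  gp <- make_gp("SLPSP", 121, 121)
  bad <- data.frame(series = "b", index = 12L, charge = 1L,
                    glycan_state = "none", mz = 100, label = "b12",
                    peak_mz = 100, peak_intensity = 1, error_ppm = 0)
  expect_error(localize_spectrum(gp, bad), "do not belong")
  expect_error(localize_spectrum(glycopeptide("SLPSP", 121), bad[0, ]),
               "no glycosites")
})

test_that("5 ppm noise, 50% coverage: recall >= 0.9 and zero false localizations", {
  gps <- fsh_ctp_glycopeptides(TRUE)
  total <- 0L; recovered <- 0L; false_loc <- 0L; n_spec <- 0L
  for (seed in 1:13) {  # 13 x 16 = 208 spectra
    truth <- ground_truth(coverage = 0.5, ppm_sd = 5, n_decoys = 0,
                          seed = 1000L + seed)
    sim <- simulate_spectra(truth)
    for (i in seq_along(sim$spectra)) {
      gp <- gps[[i]]
      a <- loc(gp, sim$spectra[[i]], tolerance_ppm = 20)
      planted <- as.integer(names(gp$site_glycans))
      ion_backed <- a$protein_position[a$evidence == "direct_bracketing"]
      total <- total + length(planted)
      recovered <- recovered + sum(planted %in% ion_backed)
      false_loc <- false_loc + sum(!ion_backed %in% planted)
      n_spec <- n_spec + 1L
    }
  }
  expect_gte(n_spec, 200L)
  expect_gte(recovered / total, 0.9)
  expect_equal(false_loc, 0L)
})
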