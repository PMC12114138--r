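## Closed-search identification and the end-to-end site pipeline, plus the
## FSH-CTP preset (protein numbering, candidate glycosites, prior-knowledge
## sites and the reported core 1 glycopeptide inventory).

#' FSH-CTP preset
#'
#' The 28-residue C-terminal peptide (CTP) of the hCG beta-subunit carried
#' by rhFSH-CTP, numbered 112-139 as in the FSH-CTP fusion. `glycosites`
#' are the seven characterized O-glycosylation positions (including S124);
#' `prior_sites` are the six previously reported ones, so S124 is flagged
#' novel by [aggregate_sites()]. `allowed_glycans` is the core 1 glycan set
#' used for closed searches (core 1 and its mono-/disialylated forms);
#' sialidase co-treatment collapses all three to plain core 1.
#'
#' @return List with `sequence`, `offset`, `glycosites`, `prior_sites`,
#'   `allowed_glycans`, and `inventory` (see [fsh_ctp_glycopeptides()]).
#' @export
fsh_ctp_preset <- function() {
  list(
    sequence = "SSSSKAPPPSLPSPSRLPGPSDTPILPQ",
    offset = 112L,
    glycosites = c(114L, 115L, 121L, 124L, 126L, 132L, 134L),
    prior_sites = c(114L, 115L, 121L, 126L, 132L, 134L),
    allowed_glycans = list(
      glycan_composition(HexNAc = 1, Hex = 1),
      glycan_composition(HexNAc = 1, Hex = 1, NeuAc = 1),
      glycan_composition(HexNAc = 1, Hex = 1, NeuAc = 2)),
    inventory = fsh_ctp_glycopeptides())
}

#' Reported FSH-CTP core 1 glycopeptide inventory
#'
#' The 16 OpeRATOR/sialidase glycopeptides detected on the CTP by EThcD
#' LC-MS/MS, each carrying core 1 (HexNAc1Hex1) at the listed sites, with
#' the charge state they were observed at. Locations are recomputed from the
#' sequences (two printed locations in the source table are internally
#' inconsistent with the sequence lengths).
#'
#' @param as_glycopeptides Return a list of [glycopeptide()] objects (core 1
#'   at every listed site) instead of the data.frame.
#' @return data.frame with columns `sequence`, `start`, `end`, `sites`
#'   (comma-separated protein positions), `charge` — or a list of
#'   glycopeptides with a `charge` attribute.
#' @export
fsh_ctp_glycopeptides <- function(as_glycopeptides = FALSE) {
  inv <- data.frame(
    sequence = c("SKAPPPSLP", "SLPSP", "SRLPGPSDTPILPQ", "SDTPILPQ",
                 "TPILPQ", "SLPSPSRLPGP", "SSKAPPP", "SSKAPPPSLP",
                 "SSKAPPPSLP", "SKAPPPSLPSP", "SRLPGPSDTPILPQ",
                 "SLPSPSRLPGPSDTPILPQ", "SSKAPPPSLPSP", "SSKAPPPSLPSP",
                 "SRLPGPSDTPILPQ", "SPSRLPGPSDTPILPQ"),
    start = c(115L, 121L, 126L, 132L, 134L, 121L, 114L, 114L, 114L, 115L,
              126L, 121L, 114L, 114L, 126L, 124L),
    sites = c("115", "121", "126", "132", "134", "121", "114,115",
              "114,115", "114,121", "115,121", "126,132", "121,132",
              "114,124", "114,115,121", "126,132,134", "124,126,132"),
    charge = c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 3L, 2L, 3L,
               3L, 3L))
  inv$end <- inv$start + nchar(inv$sequence) - 1L
  inv <- inv[c("sequence", "start", "end", "sites", "charge")]
  if (!as_glycopeptides) return(inv)
  core1 <- glycan_composition(HexNAc = 1, Hex = 1)
  lapply(seq_len(nrow(inv)), function(i) {
    pos <- as.integer(strsplit(inv$sites[i], ",")[[1]])
    gp <- glycopeptide(inv$sequence[i], inv$start[i],
                       setNames(rep(list(core1), length(pos)), pos))
    attr(gp, "charge") <- inv$charge[i]
    gp
  })
}

#' Closed-search glycopeptide identification
#'
#' For each spectrum, candidates within the precursor tolerance (at the
#' spectrum's charge) are scored by the number of theoretical backbone ions
#' matched within the fragment tolerance; the best-scoring candidate is
#' reported. Ties break deterministically by smaller absolute precursor
#' error, then fewer glycosites, then lexicographic order.
#'
#' @param spectra List of [spectrum()] objects.
#' @param candidates List of [glycopeptide()] objects (e.g. from
#'   [digest_operator()] + [enumerate_glycoforms()]).
#' @param precursor_ppm,fragment_ppm Mass tolerances (defaults 10 / 20 ppm).
#' @param mode `"EThcD"` or `"HCD"`.
#' @param z_convention z-ion convention for EThcD.
#' @param min_matched Minimum matched backbone ions to accept an
#'   identification (default 1; precursor-only spectra stay unidentified).
#' @return List with `results` (data.frame: one row per identified spectrum)
#'   and `glycopeptides` (the matched candidate objects, parallel to rows).
#' @export
identify_spectra <- function(spectra, candidates, precursor_ppm = 10,
                             fragment_ppm = 20, mode = c("EThcD", "HCD"),
                             z_convention = "z_dot", min_matched = 1L) {
  mode <- match.arg(mode)
  rows <- list(); gps <- list()
  cand_key <- vapply(candidates, format, character(1))
  for (spec in spectra) {
    prec <- vapply(candidates, gp_precursor_mz, numeric(1),
                   charge = spec$precursor_charge)
    perr <- ppm_error(spec$precursor_mz, prec)
    hits <- which(abs(perr) <= precursor_ppm)
    if (!length(hits)) next
    score <- vapply(hits, function(j) {
      ions <- theoretical_ions(candidates[[j]], mode = mode,
                               z_convention = z_convention)
      nrow(match_peaks(spec, ions, tolerance_ppm = fragment_ppm))
    }, numeric(1))
    ord <- order(-score, abs(perr[hits]),
                 vapply(hits, function(j) length(candidates[[j]]$site_glycans),
                        integer(1)),
                 cand_key[hits])
    best <- hits[ord[1]]
    if (score[ord[1]] < min_matched) next
    gp <- candidates[[best]]
    rows[[length(rows) + 1L]] <- data.frame(
      spectrum_id = spec$id, sequence = gp$sequence, start = gp$start,
      end = gp$end,
      sites = paste(names(gp$site_glycans), collapse = ","),
      charge = spec$precursor_charge,
      precursor_mz = spec$precursor_mz,
      precursor_ppm = perr[best],
      n_matched = as.integer(score[ord[1]]))
    gps[[length(gps) + 1L]] <- gp
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spectrum_id = character(), sequence = character(),
               start = integer(), end = integer(), sites = character(),
               charge = integer(), precursor_mz = numeric(),
               precursor_ppm = numeric(), n_matched = integer())
  rownames(results) <- NULL
  list(results = results, glycopeptides = gps)
}

#' Build the closed-search candidate list for a protein
#'
#' Digest with OpeRATOR specificity, then enumerate glycoforms over the
#' allowed glycan set with unoccupied internal sites permitted (an uncut
#' internal S/T need not carry a glycan). When `sialidase = TRUE` (the
#' default, mirroring the wet protocol) the allowed list is desialylated
#' first.
#'
#' @inheritParams digest_operator
#' @param allowed List of allowed [glycan_composition()] objects.
#' @param sialidase Desialylate the allowed list before enumeration.
#' @return List of [glycopeptide()] objects.
#' @export
build_candidates <- function(sequence, glycosites, allowed, max_missed = 3L,
                             mode = c("specific", "semi_specific"),
                             offset = 1L, sialidase = TRUE) {
  mode <- match.arg(mode)
  if (sialidase) allowed <- apply_sialidase(allowed)
  # span generation is unconstrained: the missed-cleavage budget applies to
  # occupied internal sites, which are only fixed once a glycoform is chosen
  spans <- digest_operator(sequence, glycosites,
                           max_missed = length(glycosites), mode, offset)
  spans <- spans[spans$is_glycopeptide, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(spans)))
    out <- c(out, enumerate_glycoforms(spans[i, ], glycosites, allowed,
                                       internal_optional = TRUE))
  out[vapply(out, function(gp) gp$missed_cleavages <= max_missed, logical(1))]
}

#' End-to-end site localization pipeline
#'
#' Digest, enumerate, identify, localize and aggregate in one call.
#'
#' @param spectra List of [spectrum()] objects.
#' @param sequence,glycosites,offset Protein and candidate sites.
#' @param allowed Allowed glycan compositions (default: FSH-CTP core 1 set).
#' @param prior_sites Prior-knowledge sites for the novelty flag.
#' @param mode Fragmentation mode for identification and localization.
#' @param max_missed,precursor_ppm,fragment_ppm Search parameters
#'   (defaults 3, 10, 20).
#' @param enzyme_rule Use OpeRATOR N-terminal inference as evidence
#'   fallback.
#' @return List with `identifications`, `assignments` (per-spectrum site
#'   evidence) and `site_table` (aggregated, with novelty flags).
#' @export
run_site_pipeline <- function(spectra, sequence, glycosites, offset = 1L,
                              allowed = fsh_ctp_preset()$allowed_glycans,
                              prior_sites = integer(),
                              mode = c("EThcD", "HCD"), max_missed = 3L,
                              precursor_ppm = 10, fragment_ppm = 20,
                              enzyme_rule = TRUE) {
  mode <- match.arg(mode)
  candidates <- build_candidates(sequence, glycosites, allowed,
                                 max_missed = max_missed, offset = offset)
  ids <- identify_spectra(spectra, candidates, precursor_ppm, fragment_ppm,
                          mode = mode)
  spec_by_id <- setNames(spectra, vapply(spectra, `[[`, character(1), "id"))
  assignments <- list()
  for (i in seq_len(nrow(ids$results))) {
    gp <- ids$glycopeptides[[i]]
    spec <- spec_by_id[[ids$results$spectrum_id[i]]]
    matches <- match_peaks(spec, theoretical_ions(gp, mode = mode),
                           tolerance_ppm = fragment_ppm)
    assignments[[i]] <- localize_spectrum(gp, matches, mode = mode,
                                          enzyme_rule = enzyme_rule,
                                          spectrum_id = spec$id)
  }
  assignments <- if (length(assignments)) do.call(rbind, assignments) else NULL
  list(identifications = ids$results,
       assignments = assignments,
       site_table = aggregate_sites(assignments, prior_sites))
}
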