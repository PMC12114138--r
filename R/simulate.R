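## Ground-truthed synthetic data for every pipeline stage. The generator's
## defaults are the conditions of the underlying validation experiments:
## 10/20 ppm-class instruments (Gaussian ppm mass error), six replicates at
## ~1% CV, a 10-100 ug dilution series with a 40 ug reference, ~3% peeling
## and ~1% mono-deacetylation byproduct fractions.

#' Ground truth for synthetic data generation
#'
#' @param sequence,offset Protein (default: the FSH-CTP CTP, offset 112).
#' @param glycopeptides List of [glycopeptide()] objects with optional
#'   `charge` attributes (default: the reported 16-glycopeptide inventory).
#' @param mode Fragmentation mode simulated.
#' @param coverage Fraction of theoretical backbone ions emitted per
#'   spectrum, in `[0, 1]`.
#' @param ppm_sd Gaussian fragment/precursor mass error sd, in ppm.
#' @param n_decoys Uniform decoy peaks added per spectrum.
#' @param proportions Named percentages of the four major glycoforms
#'   (must sum to 100).
#' @param byproduct_fractions Named fractions (of total major area) for
#'   byproduct species present in [glycan_library()].
#' @param cv Multiplicative (lognormal) area CV for replicates.
#' @param n_replicates Replicate count for the reproducibility table.
#' @param amounts Protein amounts (ug) of the dilution series.
#' @param seed Integer seed; identical ground truth implies identical output.
#' @return List of class `oglyco_truth`.
#' @export
ground_truth <- function(sequence = fsh_ctp_preset()$sequence,
                         offset = fsh_ctp_preset()$offset,
                         glycopeptides = fsh_ctp_glycopeptides(TRUE),
                         mode = c("EThcD", "HCD"),
                         coverage = 1, ppm_sd = 0, n_decoys = 0L,
                         proportions = c("GalGalNAc" = 10,
                                         "NeuAcGalGalNAc" = 30,
                                         "Gal(NeuAcGalNAc)" = 15,
                                         "NeuAcGal(NeuAcGalNAc)" = 45),
                         byproduct_fractions = c("NeuAcGal" = 0.03,
                                                 "NeuAc" = 0.03,
                                                 "NeuAcGalGalNAc-deAc" = 0.01,
                                                 "NeuAcGal(NeuAcGalNAc)-deAc" = 0.01),
                         cv = 0.01, n_replicates = 6L,
                         amounts = c(10, 20, 40, 60, 100),
                         seed = 1L) {
  mode <- match.arg(mode)
  if (coverage < 0 || coverage > 1) stop("coverage must be in [0, 1]")
  if (abs(sum(proportions) - 100) > 1e-9) stop("proportions must sum to 100")
  structure(list(sequence = sequence, offset = offset,
                 glycopeptides = glycopeptides, mode = mode,
                 coverage = coverage, ppm_sd = ppm_sd,
                 n_decoys = as.integer(n_decoys),
                 proportions = proportions,
                 byproduct_fractions = byproduct_fractions, cv = cv,
                 n_replicates = as.integer(n_replicates), amounts = amounts,
                 seed = as.integer(seed)),
            class = "oglyco_truth")
}

## rank-based intensity model (arbitrary; no intensity model is claimed):
## C-terminal series > N-terminal series > remnant states
.ion_base_intensity <- function(series, glycan_state) {
  base <- ifelse(series %in% c("y", "z", "z_dot", "z_plus1"), 100, 60)
  ifelse(glycan_state == "hexnac_remnant", 30, base)
}

#' Simulate glycopeptide MS/MS spectra
#'
#' One spectrum per ground-truth glycopeptide: the precursor and a seeded
#' random subset (`coverage`) of its theoretical ions, perturbed by Gaussian
#' ppm error, plus uniform decoy peaks whose intensities are drawn from the
#' real-ion intensity distribution.
#'
#' @param truth A [ground_truth()] object.
#' @return List with `spectra` (list of [spectrum()]), `spectrum_truth`
#'   (data.frame: id, sequence, start, sites, charge, theoretical precursor)
#'   and `ion_truth` (data.frame of every planted ion).
#' @export
simulate_spectra <- function(truth) {
  stopifnot(inherits(truth, "oglyco_truth"))
  set.seed(truth$seed)
  spectra <- list(); strows <- list(); ionrows <- list()
  for (i in seq_along(truth$glycopeptides)) {
    gp <- truth$glycopeptides[[i]]
    charge <- attr(gp, "charge")
    if (is.null(charge)) charge <- 2L
    id <- sprintf("sim_%02d_%s", i, gp$sequence)
    prec_theo <- gp_precursor_mz(gp, charge)
    prec_obs <- prec_theo * (1 + rnorm(1, 0, truth$ppm_sd) * 1e-6)
    ions <- theoretical_ions(gp, mode = truth$mode)
    keep <- as.logical(rbinom(nrow(ions), 1L, truth$coverage))
    emitted <- ions[keep, , drop = FALSE]
    if (nrow(emitted) == 0L && truth$n_decoys == 0L)
      warning("spectrum ", id, " is empty (coverage 0 and no decoys)")
    int <- .ion_base_intensity(emitted$series, emitted$glycan_state) *
      exp(rnorm(nrow(emitted), 0, 0.3))
    mz <- emitted$mz * (1 + rnorm(nrow(emitted), 0, truth$ppm_sd) * 1e-6)
    peaks <- data.frame(mz = mz, intensity = int)
    if (truth$n_decoys > 0L) {
      hi <- max(c(emitted$mz, prec_theo * charge))
      dmz <- runif(truth$n_decoys, 100, hi)
      dint <- if (nrow(emitted)) sample(int, truth$n_decoys, replace = TRUE)
              else runif(truth$n_decoys, 10, 100)
      peaks <- rbind(peaks, data.frame(mz = dmz, intensity = dint))
    }
    spectra[[i]] <- spectrum(prec_obs, charge, peaks, id = id)
    strows[[i]] <- data.frame(
      spectrum_id = id, sequence = gp$sequence, start = gp$start,
      sites = paste(names(gp$site_glycans), collapse = ","),
      charge = charge, precursor_theoretical = prec_theo)
    if (nrow(emitted))
      ionrows[[length(ionrows) + 1L]] <- cbind(spectrum_id = id, emitted)
  }
  list(spectra = spectra,
       spectrum_truth = do.call(rbind, strows),
       ion_truth = if (length(ionrows)) do.call(rbind, ionrows) else NULL)
}

#' Simulate released-glycan area tables
#'
#' Species areas follow `response * amount * proportion` with multiplicative
#' lognormal noise of the configured CV; byproducts are added at fixed
#' fractions of the total major-glycan area. Three tables are produced:
#' replicates (n at 60 ug), stability timepoints (0/12/24/48 h at 60 ug) and
#' the dilution series over `amounts`.
#'
#' @param truth A [ground_truth()] object.
#' @param response Fluorescence response per ug of protein (arbitrary area
#'   units; all downstream metrics are scale-invariant).
#' @return List of data.frames `replicates`, `stability`, `dilution`, each in
#'   ChromPeak layout (`sample_id`, `rt`, `mz`, `area`, `protein_amount`).
#' @export
simulate_profile_tables <- function(truth, response = 1000) {
  stopifnot(inherits(truth, "oglyco_truth"))
  set.seed(truth$seed + 1L)
  lib <- glycan_library()
  noise <- function(n) {
    if (truth$cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + truth$cv^2))
    exp(rnorm(n, -sdlog^2 / 2, sdlog))
  }
  one_sample <- function(sample_id, amount) {
    major_area <- response * amount * truth$proportions / 100 *
      noise(length(truth$proportions))
    total_major <- sum(major_area)
    by_area <- total_major * truth$byproduct_fractions *
      noise(length(truth$byproduct_fractions))
    areas <- c(major_area, by_area)
    idx <- match(names(areas), lib$name)
    data.frame(sample_id = sample_id, rt = lib$rt[idx], mz = lib$mz[idx],
               area = unname(areas), protein_amount = amount,
               species_truth = names(areas))
  }
  replicates <- do.call(rbind, lapply(seq_len(truth$n_replicates), function(r)
    one_sample(sprintf("rep_%d", r), 60)))
  stability <- do.call(rbind, lapply(c(0, 12, 24, 48), function(h)
    one_sample(sprintf("t%02dh", h), 60)))
  dilution <- do.call(rbind, lapply(truth$amounts, function(a)
    one_sample(sprintf("amount_%g", a), a)))
  rownames(replicates) <- rownames(stability) <- rownames(dilution) <- NULL
  list(replicates = replicates, stability = stability, dilution = dilution)
}
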