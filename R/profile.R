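## Released 2-AB glycan profiling: chromatogram peak assignment against a
## composition library (including peeling and mono-deacetylation byproducts)
## and the standard validation metrics: normalized peak-area percentages,
## replicate RSD, dilution-series linearity and recovery rate.

#' Built-in 2-AB O-glycan species library
#'
#' The core 1 derived glycoforms observed on the CTP, plus the known release
#' byproducts: peeling products (reducing-end degradation, no HexNAc left)
#' and mono-deacetylated (-42.0106 Da) variants of the sialylated species.
#' The two monosialylated core 1 isomers share one m/z (795.32) and are only
#' separable by retention time. Retention times are typical HILIC values for
#' these species (minutes) and act as defaults for isomer windows.
#'
#' @return data.frame with columns `name`, `HexNAc`, `Hex`, `NeuAc`, `state`,
#'   `category`, `rt`, `mz` (singly protonated, 2-AB labeled).
#' @export
glycan_library <- function() {
  lib <- data.frame(
    name = c("GalGalNAc", "NeuAcGalGalNAc", "Gal(NeuAcGalNAc)",
             "NeuAcGal(NeuAcGalNAc)", "NeuAcGal", "NeuAc",
             "NeuAcGalGalNAc-deAc", "NeuAcGal(NeuAcGalNAc)-deAc"),
    HexNAc = c(1, 1, 1, 1, 0, 0, 1, 1),
    Hex    = c(1, 1, 1, 1, 1, 0, 1, 1),
    NeuAc  = c(0, 1, 1, 2, 1, 1, 1, 2),
    state = c(rep("intact", 6), rep("mono_deacetylated", 2)),
    category = c(rep("major_glycan", 4), rep("peeling_byproduct", 2),
                 rep("deacetylation_byproduct", 2)),
    rt = c(7.98, 12.94, 13.77, 15.97, 11.06, 11.51, 15.05, 17.21))
  lib$mz <- vapply(seq_len(nrow(lib)), function(i) {
    sp <- glycan_species(
      glycan_composition(HexNAc = lib$HexNAc[i], Hex = lib$Hex[i],
                         NeuAc = lib$NeuAc[i]),
      label = "two_AB", state = lib$state[i], short_name = lib$name[i])
    labeled_glycan_mz(sp, 1L)
  }, numeric(1))
  lib
}

#' Assign chromatogram peaks to glycan species
#'
#' Each peak carrying an observed m/z is matched to the nearest library
#' species within tolerance. Species with indistinguishable m/z (isomers)
#' are disambiguated by retention-time windows; a peak inside none (or
#' several) of the windows is labeled as an isomer group.
#'
#' @param peaks data.frame with columns `rt` (min), `area`, and optionally
#'   `mz`, `sample_id`, `protein_amount`.
#' @param library A [glycan_library()]-shaped data.frame.
#' @param tolerance_da Absolute m/z tolerance (default 0.02 Da).
#' @param rt_window Half-width (min) of the retention-time window around each
#'   library species used for isomer disambiguation.
#' @return `peaks` with added `species`, `category`, `theoretical_mz`,
#'   `error_ppm` columns; unmatched peaks get `species = "unassigned"`.
#' @export
assign_glycan_peaks <- function(peaks, library = glycan_library(),
                                tolerance_da = 0.02, rt_window = 0.4) {
  if (is.null(library) || nrow(library) == 0L) stop("empty glycan library")
  out <- peaks
  out$species <- "unassigned"
  out$category <- "unassigned"
  out$theoretical_mz <- NA_real_
  out$error_ppm <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (!"mz" %in% names(out) || is.na(out$mz[i])) next
    d <- abs(library$mz - out$mz[i])
    cand <- which(d <= tolerance_da)
    if (!length(cand)) next
    cand <- cand[d[cand] <= min(d[cand]) + 1e-9]  # isomers: equal-mass set
    if (length(cand) > 1L && !is.na(out$rt[i])) {
      in_win <- cand[abs(library$rt[cand] - out$rt[i]) <= rt_window]
      if (length(in_win) == 1L) cand <- in_win
    }
    if (length(cand) == 1L) {
      out$species[i] <- library$name[cand]
      out$category[i] <- library$category[cand]
    } else {
      out$species[i] <- paste0("isomer_group[",
                               paste(library$name[cand], collapse = "|"), "]")
      out$category[i] <- library$category[cand[1]]
    }
    out$theoretical_mz[i] <- library$mz[cand[1]]
    out$error_ppm[i] <- ppm_error(out$mz[i], library$mz[cand[1]])
  }
  out
}

#' Normalized peak-area percentages
#'
#' @param assignments Output of [assign_glycan_peaks()].
#' @param scope `"major_only"` (default; the four main glycoforms, matching
#'   the usual reporting) or `"all_assigned"` (includes byproducts).
#' @return Named numeric vector of percentages summing to 100.
#' @export
normalize_areas <- function(assignments, scope = c("major_only", "all_assigned")) {
  scope <- match.arg(scope)
  keep <- if (scope == "major_only") assignments$category == "major_glycan"
          else assignments$species != "unassigned"
  d <- assignments[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop("no assigned peaks in scope")
  tot <- tapply(d$area, d$species, sum)
  if (sum(tot) <= 0) stop("zero total area in scope")
  100 * tot / sum(tot)
}

#' Replicate relative standard deviation
#'
#' RSD = 100 * sample (n-1) standard deviation / mean, per species, across
#' replicate percentage tables. A species missing from a replicate is
#' treated as 0% with a warning.
#'
#' @param percentage_tables List (length >= 2) of named vectors from
#'   [normalize_areas()].
#' @return Named numeric vector of RSD percentages.
#' @export
replicate_rsd <- function(percentage_tables) {
  if (length(percentage_tables) < 2L) stop("need at least 2 replicates")
  species <- unique(unlist(lapply(percentage_tables, names)))
  mat <- vapply(percentage_tables, function(p) {
    if (!all(species %in% names(p)))
      warning("species missing from a replicate; treated as 0%")
    out <- setNames(numeric(length(species)), species)
    out[names(p)] <- p
    out
  }, numeric(length(species)))
  mat <- matrix(mat, nrow = length(species),
                dimnames = list(species, NULL))
  apply(mat, 1, function(x) 100 * sd(x) / mean(x))
}

#' Dilution-series linearity
#'
#' Ordinary least-squares regression of peak area on protein amount.
#'
#' @param series data.frame with columns `protein_amount` (ug) and `area`.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
glycan_linearity <- function(series) {
  if (length(unique(series$protein_amount)) < 3L)
    stop("need at least 3 distinct protein amounts")
  fit <- lm(area ~ protein_amount, data = series)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((series$area - mean(series$area))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}

#' Recovery rate
#'
#' `100 * measured / (reference_area * protein_amount / reference_amount)`:
#' the measured area as a percentage of the area expected from proportional
#' scaling of the reference-amount measurement (40 ug by convention).
#'
#' @param measured_area Measured peak area at `protein_amount`.
#' @param protein_amount Protein amount (ug) of the measurement.
#' @param reference_area Peak area measured at `reference_amount`.
#' @param reference_amount Reference protein amount (ug), default 40.
#' @return Recovery in percent.
#' @export
recovery_rate <- function(measured_area, protein_amount, reference_area,
                          reference_amount = 40) {
  if (any(protein_amount <= 0) || any(reference_area <= 0) ||
      any(reference_amount <= 0))
    stop("protein amounts and reference area must be positive")
  100 * measured_area / (reference_area * protein_amount / reference_amount)
}
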