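## Theoretical fragment ions for glycopeptides. HCD preferentially cleaves
## glycosidic bonds, so b/y ions are emitted naked, with a +203.08 HexNAc
## remnant per glycosite in range ("b + N" ions), or with the full glycan;
## EThcD preserves the glycan on backbone c/z fragments, so full-state ions
## are the default there.

.series_nterm <- c("b", "c")
.series_cterm <- c("y", "z", "z_dot", "z_plus1")

series_neutral_offset <- function(series) {
  k <- mass_table()$constants
  switch(series,
    b = 0,
    c = k[["nh3"]],
    y = k[["water"]],
    z = k[["water"]] + k[["z_delta"]],
    z_dot = k[["water"]] + k[["z_dot_delta"]],
    z_plus1 = k[["water"]] + k[["z_plus1_delta"]],
    stop("unknown ion series: ", series))
}

## residue range (local positions) covered by a fragment
fragment_range <- function(series, index, n) {
  if (index < 1L || index > n - 1L) stop("fragment index outside the backbone")
  if (series %in% .series_nterm) c(1L, index) else c(n - index + 1L, n)
}

#' Backbone fragment ion m/z
#'
#' b/y/c/z fragment m/z for a glycopeptide, in one of three glycan states:
#' `"full"` (residue masses of all glycans on sites inside the fragment
#' range), `"hexnac_remnant"` (+203.079373 per glycosite in range, the
#' "b + N" diagnostic), or `"none"` (naked backbone).
#'
#' z-series conventions at charge 1 relative to the y ion: `z` = y - 17.02655,
#' `z_dot` (radical, typical of ETD spectra and the default elsewhere) =
#' y - 16.01872, `z_plus1` = y - 15.01090.
#'
#' @param gp A [glycopeptide()].
#' @param series One of `"b"`, `"y"`, `"c"`, `"z"`, `"z_dot"`, `"z_plus1"`.
#' @param index Fragment index, 1 to length - 1.
#' @param charge Positive integer.
#' @param glycan_state `"none"`, `"full"` or `"hexnac_remnant"`; the latter
#'   two require at least one glycosite inside the fragment range.
#' @return m/z.
#' @export
#' @examples
#' gp <- glycopeptide("SRLPGP", 126,
#'   list(`126` = glycan_composition(HexNAc = 1, Hex = 1)))
#' backbone_ion_mz(gp, "y", 5)  # 539.33
backbone_ion_mz <- function(gp, series, index, charge = 1L,
                            glycan_state = c("none", "full", "hexnac_remnant")) {
  glycan_state <- match.arg(glycan_state)
  mt <- mass_table()
  n <- nchar(gp$sequence)
  rng <- fragment_range(series, index, n)
  letters <- strsplit(gp$sequence, "")[[1]]
  neutral <- sum(mt$residues[letters[rng[1]:rng[2]]]) +
    series_neutral_offset(series)
  local <- gp_local_sites(gp)
  in_range <- local >= rng[1] & local <= rng[2]
  if (glycan_state != "none") {
    if (!any(in_range))
      stop("glycan_state '", glycan_state,
           "' on a fragment range containing no glycosite")
    neutral <- neutral + if (glycan_state == "full") {
      sum(vapply(gp$site_glycans[in_range], glycan_mass, numeric(1)))
    } else {
      sum(in_range) * mt$constants[["hexnac_remnant"]]
    }
  }
  (neutral + charge * mt$constants[["proton"]]) / charge
}

#' Diagnostic oxonium ions
#'
#' Singly charged glycan oxonium ions (HexNAc 204.0867, HexNAcHex 366.1395,
#' NeuAc 292.1027) and their water losses.
#'
#' @return data.frame with `label` and `mz`.
#' @export
oxonium_ions <- function() {
  mt <- mass_table()
  p <- mt$constants[["proton"]]; w <- mt$constants[["water"]]
  ms <- mt$monosaccharides
  base <- c(HexNAc = unname(ms["HexNAc"]),
            HexNAcHex = unname(ms["HexNAc"] + ms["Hex"]),
            NeuAc = unname(ms["NeuAc"]))
  data.frame(
    label = c(names(base), paste0(names(base), "-H2O")),
    mz = c(base + p, base + p - w),
    row.names = NULL)
}

#' Theoretical ion set for a glycopeptide
#'
#' Enumerates fragment ions for all requested series, indices, charges and
#' glycan states. Defaults: HCD uses b/y with naked, HexNAc-remnant and full
#' states (remnant/full only where the range contains a glycosite); EThcD
#' uses c plus the configured z convention, glycan retained (`full`) wherever
#' a glycosite is in range and naked otherwise.
#'
#' @param gp A [glycopeptide()].
#' @param mode `"HCD"` or `"EThcD"`.
#' @param charges Integer vector of fragment charges (default 1).
#' @param z_convention `"z_dot"` (default), `"z"` or `"z_plus1"`.
#' @param states Optional character vector overriding the per-mode default
#'   glycan states (subset of `"none"`, `"full"`, `"hexnac_remnant"`).
#' @param oxonium Append diagnostic oxonium ions.
#' @return data.frame with columns `series`, `index`, `charge`,
#'   `glycan_state`, `mz`, `label`, duplicate-free.
#' @export
theoretical_ions <- function(gp, mode = c("HCD", "EThcD"), charges = 1L,
                             z_convention = c("z_dot", "z", "z_plus1"),
                             states = NULL, oxonium = FALSE) {
  mode <- match.arg(mode)
  z_convention <- match.arg(z_convention)
  n <- nchar(gp$sequence)
  local <- gp_local_sites(gp)
  series_set <- if (mode == "HCD") c("b", "y") else c("c", z_convention)
  if (is.null(states))
    states <- if (mode == "HCD") c("none", "hexnac_remnant", "full") else "full"
  rows <- list()
  for (series in series_set) for (index in seq_len(n - 1L)) {
    rng <- fragment_range(series, index, n)
    has_site <- any(local >= rng[1] & local <= rng[2])
    st <- if (mode == "EThcD") {
      # glycan rides along in electron-driven dissociation
      if (has_site && "full" %in% states) "full" else "none"
    } else {
      c("none"[("none" %in% states) || !has_site],
        intersect(states, c("hexnac_remnant", "full"))[has_site])
    }
    st <- unique(st[!is.na(st)])
    if (!length(st)) st <- "none"
    for (state in st) {
      if (state != "none" && !has_site) next
      for (ch in charges) {
        rows[[length(rows) + 1L]] <- data.frame(
          series = series, index = index, charge = as.integer(ch),
          glycan_state = state,
          mz = backbone_ion_mz(gp, series, index, ch, state))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$label <- sprintf("%s%d%s%s", out$series, out$index,
                       c(none = "", full = "+G", hexnac_remnant = "+N")[out$glycan_state],
                       ifelse(out$charge > 1, sprintf("(%d+)", out$charge), ""))
  out <- out[!duplicated(out[c("series", "index", "charge", "glycan_state")]), ]
  if (oxonium) {
    ox <- oxonium_ions()
    out <- rbind(out, data.frame(series = "oxonium", index = NA_integer_,
                                 charge = 1L, glycan_state = "none",
                                 mz = ox$mz, label = ox$label))
  }
  rownames(out) <- NULL
  out
}

#' MS/MS spectrum container
#'
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Positive integer.
#' @param peaks data.frame with columns `mz` and `intensity` (>= 0); sorted
#'   by m/z on construction.
#' @param id Spectrum identifier.
#' @return An object of class `oglyco_spectrum`.
#' @export
spectrum <- function(precursor_mz, precursor_charge, peaks, id = "spectrum") {
  if (precursor_charge < 1) stop("precursor_charge must be >= 1")
  if (is.null(peaks) || nrow(peaks) == 0L)
    peaks <- data.frame(mz = numeric(), intensity = numeric())
  if (any(peaks$intensity < 0)) stop("peak intensities must be >= 0")
  peaks <- peaks[order(peaks$mz), c("mz", "intensity")]
  rownames(peaks) <- NULL
  structure(list(id = id, precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 peaks = peaks), class = "oglyco_spectrum")
}

#' @export
print.oglyco_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s> precursor %.4f (%d+), %d peaks\n",
              x$id, x$precursor_mz, x$precursor_charge, nrow(x$peaks)))
  invisible(x)
}

#' Match theoretical ions against an observed peak list
#'
#' Each theoretical ion is matched to the nearest peak (by absolute ppm
#' error) within tolerance; exact ties go to the higher-intensity peak. One
#' peak may satisfy multiple ions. Intensity plays no role in identity
#' decisions beyond tie-breaking.
#'
#' @param spec An [spectrum()] object.
#' @param ions data.frame from [theoretical_ions()] (needs an `mz` column).
#' @param tolerance_ppm Fragment tolerance in ppm (default 20).
#' @param tolerance_da Optional absolute tolerance in Da; if supplied it is
#'   used instead of the ppm tolerance.
#' @return The matched subset of `ions` with added `peak_mz`,
#'   `peak_intensity` and `error_ppm` columns.
#' @export
match_peaks <- function(spec, ions, tolerance_ppm = 20, tolerance_da = NULL) {
  stopifnot(inherits(spec, "oglyco_spectrum"))
  pk <- spec$peaks
  hits <- lapply(seq_len(nrow(ions)), function(i) {
    theo <- ions$mz[i]
    if (nrow(pk) == 0L) return(NULL)
    err_ppm <- ppm_error(pk$mz, theo)
    within <- if (is.null(tolerance_da)) abs(err_ppm) <= tolerance_ppm
              else abs(pk$mz - theo) <= tolerance_da
    if (!any(within)) return(NULL)
    cand <- which(within)
    best <- cand[order(abs(err_ppm[cand]), -pk$intensity[cand])][1]
    cbind(ions[i, , drop = FALSE],
          data.frame(peak_mz = pk$mz[best], peak_intensity = pk$intensity[best],
                     error_ppm = err_ppm[best]))
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits))
    return(cbind(ions[0, , drop = FALSE],
                 data.frame(peak_mz = numeric(), peak_intensity = numeric(),
                            error_ppm = numeric())))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
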