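## Site localization with explicit evidence tiers.
##
## Confidence criteria for HCD follow the field practice for OpeRATOR
## products: (1) a backbone fragment from a peptide with a single candidate
## S/T ("single_candidate") and (2) retention of at least one core GalNAc on
## a fragment whose range isolates the site ("remnant_localized"). EThcD
## backbone ions retain the glycan, so consecutive (or terminal) c/z ions
## can bracket the mass shift to one residue ("direct_bracketing"). When no
## ion evidence exists, the N-terminal residue of an OpeRATOR product may be
## inferred glycosylated from the enzyme's specificity alone
## ("enzyme_inferred"); everything else is "ambiguous". Evidence is reported,
## never silently upgraded.

#' Evidence tiers, best first
#' @export
evidence_levels <- function() {
  c("direct_bracketing", "single_candidate", "remnant_localized",
    "enzyme_inferred", "ambiguous")
}

## Cut-point constraint logic. A matched N-terminal ion (b/c) at index k
## fixes the glycan content of prefix 1..k (under the candidate site map);
## a matched C-terminal ion (y/z*) of suffix length j fixes prefix 1..(n-j).
## Prefix 0 and n are always known (0 and the precursor-determined total).
## Between two known cuts, if the candidate map places g >= 1 glycans in the
## region and the region contains exactly g S/T residues, every S/T in the
## region must be occupied: those sites are ion-confirmed.
confirmed_sites <- function(gp, matches, mode) {
  n <- nchar(gp$sequence)
  letters <- strsplit(gp$sequence, "")[[1]]
  st_pos <- which(letters %in% c("S", "T"))
  local_sites <- gp_local_sites(gp)
  if (nrow(matches) == 0L) return(integer())
  backbone <- matches[matches$series %in% c(.series_nterm, .series_cterm), ,
                      drop = FALSE]
  if (mode == "HCD")  # naked HCD ions cannot prove glycan location
    backbone <- backbone[backbone$glycan_state %in% c("full", "hexnac_remnant"), ,
                         drop = FALSE]
  if (nrow(backbone) == 0L) return(integer())
  cut <- ifelse(backbone$series %in% .series_nterm,
                backbone$index, n - backbone$index)
  cuts <- sort(unique(c(0L, cut, n)))
  conf <- integer()
  for (i in seq_len(length(cuts) - 1L)) {
    a <- cuts[i]; b <- cuts[i + 1L]
    region <- (a + 1L):b
    g <- sum(local_sites %in% region)
    n_st <- sum(st_pos %in% region)
    if (g >= 1L && g == n_st)
      conf <- c(conf, intersect(local_sites, region))
  }
  sort(unique(conf))
}

#' Localize glycosites from matched fragments of one spectrum
#'
#' Assigns the strongest achievable evidence tier to every glycosite of the
#' candidate glycopeptide, given the matched ions.
#'
#' @param gp The candidate [glycopeptide()] the matches were computed for.
#' @param matches Output of [match_peaks()] on ions of the same glycopeptide.
#' @param mode `"HCD"` or `"EThcD"` (controls which tiers are achievable and
#'   which ions count as localizing evidence).
#' @param enzyme_rule With OpeRATOR digestion the span's N-terminal residue
#'   is glycosylated by construction; when `TRUE`, such sites fall back to
#'   `enzyme_inferred` instead of `ambiguous` when ion evidence is absent.
#' @param spectrum_id Carried into the output.
#' @return data.frame with one row per glycosite: `protein_position`,
#'   `residue`, `composition`, `evidence`, `n_supporting_ions`,
#'   `glycopeptide`, `spectrum_id`.
#' @export
localize_spectrum <- function(gp, matches, mode = c("EThcD", "HCD"),
                              enzyme_rule = TRUE, spectrum_id = "spectrum") {
  mode <- match.arg(mode)
  if (!inherits(gp, "glycopeptide")) stop("gp must be a glycopeptide")
  if (!length(gp$site_glycans)) stop("glycopeptide carries no glycosites")
  if (nrow(matches) > 0 && any(matches$index >= nchar(gp$sequence), na.rm = TRUE))
    stop("matches do not belong to this glycopeptide (index out of range)")
  n <- nchar(gp$sequence)
  letters <- strsplit(gp$sequence, "")[[1]]
  local_sites <- gp_local_sites(gp)
  single_st <- sum(letters %in% c("S", "T")) == 1L
  n_backbone <- if (nrow(matches)) sum(!matches$series %in% "oxonium") else 0L
  conf <- confirmed_sites(gp, matches, mode)
  rows <- lapply(seq_along(local_sites), function(i) {
    lp <- local_sites[i]
    evidence <- if (mode == "HCD" && single_st && n_backbone >= 1L) {
      "single_candidate"
    } else if (lp %in% conf) {
      if (mode == "EThcD") "direct_bracketing" else "remnant_localized"
    } else if (enzyme_rule && lp == 1L) {
      "enzyme_inferred"
    } else "ambiguous"
    data.frame(protein_position = gp$start + lp - 1L,
               residue = letters[lp],
               composition = format(gp$site_glycans[[i]]),
               evidence = evidence,
               n_supporting_ions = n_backbone,
               glycopeptide = format(gp),
               spectrum_id = spectrum_id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-spectrum site assignments into a protein site table
#'
#' One row per distinct protein position, keeping the best evidence tier
#' observed across spectra, the number of distinct supporting glycopeptides,
#' and a novelty flag against a prior-knowledge site list.
#'
#' @param assignments Row-bound output of [localize_spectrum()] calls sharing
#'   one protein coordinate system.
#' @param prior_sites Integer positions previously reported as glycosylated;
#'   a position absent from this list is flagged `novel`.
#' @return data.frame with columns `position`, `residue`, `evidence`,
#'   `n_glycopeptides`, `n_spectra`, `novel`, sorted by position.
#' @export
aggregate_sites <- function(assignments, prior_sites = integer()) {
  if (is.null(assignments) || nrow(assignments) == 0L)
    return(data.frame(position = integer(), residue = character(),
                      evidence = character(), n_glycopeptides = integer(),
                      n_spectra = integer(), novel = logical()))
  lev <- evidence_levels()
  rows <- lapply(split(assignments, assignments$protein_position), function(d) {
    if (length(unique(d$residue)) > 1L)
      stop("conflicting residue letters at position ", d$protein_position[1])
    data.frame(position = d$protein_position[1],
               residue = d$residue[1],
               evidence = lev[min(match(d$evidence, lev))],
               n_glycopeptides = length(unique(d$glycopeptide)),
               n_spectra = length(unique(d$spectrum_id)),
               novel = !d$protein_position[1] %in% prior_sites)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  out
}
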