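## Monoisotopic mass arithmetic. Every other module computes masses only
## through the functions in this file.

#' Monoisotopic mass table
#'
#' Residue masses for the 20 standard amino acids, monosaccharide residue
#' masses, chemical constants and the variable modifications used throughout
#' the package. All values are monoisotopic and in Daltons.
#'
#' The 2-AB constant is the *net* mass added by reductive amination of a free
#' reducing glycan with 2-aminobenzamide (+C7H8N2O - H2O + H2 = +120.068748).
#' The proton mass (1.0072765, not the hydrogen atom mass) is used for all
#' charging arithmetic.
#'
#' @return A list with components `residues` (named numeric, 20 letters),
#'   `monosaccharides` (HexNAc, Hex, NeuAc, Fuc residue masses), `constants`
#'   (water, proton, two_ab_net, acetyl, hexnac_remnant, nh3, z_dot_delta,
#'   z_plus1_delta) and `variable_mods` (oxidation, deamidation).
#' @export
#' @examples
#' mass_table()$constants["proton"]
mass_table <- function() {
  list(
    residues = c(
      G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
      V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
      I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
      K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
      F = 147.06841392, R = 156.10111102, Y = 163.06332853, W = 186.07931295),
    monosaccharides = c(
      HexNAc = 203.079373, Hex = 162.052824, NeuAc = 291.095417,
      Fuc = 146.057909),
    constants = c(
      water = 18.010565, proton = 1.0072765, two_ab_net = 120.068748,
      acetyl = 42.010565, hexnac_remnant = 203.079373, nh3 = 17.026549,
      # z-series deltas relative to the y ion at the same suffix length
      z_delta = -17.026549, z_dot_delta = -16.018724,
      z_plus1_delta = -15.010899),
    variable_mods = c(oxidation = 15.995, deamidation = 0.9804)
  )
}

#' Glycan composition
#'
#' A named count vector over the monosaccharide alphabet {HexNAc, Hex, NeuAc,
#' Fuc}. At least one count must be positive.
#'
#' @param HexNAc,Hex,NeuAc,Fuc Non-negative integer counts.
#' @return An object of class `glycan_composition` (named integer vector).
#' @export
#' @examples
#' core1 <- glycan_composition(HexNAc = 1, Hex = 1)
glycan_composition <- function(HexNAc = 0, Hex = 0, NeuAc = 0, Fuc = 0) {
  counts <- c(HexNAc = HexNAc, Hex = Hex, NeuAc = NeuAc, Fuc = Fuc)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("glycan counts must be non-negative integers")
  if (sum(counts) < 1)
    stop("empty glycan composition: at least one monosaccharide count must be > 0")
  structure(as.integer(counts), names = names(counts),
            class = "glycan_composition")
}

#' @export
format.glycan_composition <- function(x, ...) {
  nz <- x[x > 0]
  paste0(names(nz), "(", nz, ")", collapse = "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition>", format(x), "\n")
  invisible(x)
}

is_glycan_composition <- function(x) inherits(x, "glycan_composition")

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water, plus any variable modification
#' deltas. This is the quantity instrument reports print as the "theoretical
#' mass of the unmodified peptide segment" (e.g. 625.3547 for SRLPGP).
#'
#' @param sequence Character scalar of one-letter residue codes.
#' @param mods Optional data.frame with columns `position` (1-based, within
#'   the sequence) and `mod` (a name in `mass_table()$variable_mods`).
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_mass("SRLPGP")  # 625.3547
peptide_mass <- function(sequence, mods = NULL) {
  mt <- mass_table()
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop("sequence must be a non-empty character scalar")
  letters <- strsplit(sequence, "")[[1]]
  known <- letters %in% names(mt$residues)
  if (!all(known))
    stop(sprintf("unknown residue letter '%s' at position %d",
                 letters[!known][1], which(!known)[1]))
  m <- sum(mt$residues[letters]) + mt$constants[["water"]]
  if (!is.null(mods) && nrow(mods) > 0) {
    if (any(mods$position < 1 | mods$position > length(letters)))
      stop("modification position outside the sequence")
    if (!all(mods$mod %in% names(mt$variable_mods)))
      stop("unknown variable modification name")
    m <- m + sum(mt$variable_mods[mods$mod])
  }
  unname(m)
}

#' Neutral glycan mass
#'
#' @param comp A [glycan_composition()].
#' @param form `"residue"` (as attached to a peptide) or `"free_reducing"`
#'   (released glycan; adds one water).
#' @return Neutral monoisotopic mass in Da.
#' @export
glycan_mass <- function(comp, form = c("residue", "free_reducing")) {
  form <- match.arg(form)
  mt <- mass_table()
  if (!is_glycan_composition(comp)) stop("comp must be a glycan_composition")
  m <- sum(as.integer(comp) * mt$monosaccharides[names(comp)])
  if (form == "free_reducing") m <- m + mt$constants[["water"]]
  unname(m)
}

#' Glycan species
#'
#' A glycan composition plus its labeling and chemical state, as observed in
#' released-glycan profiling: optionally 2-AB labeled and optionally
#' mono-deacetylated (loss of one acetyl from a NeuAc, a minor byproduct of
#' alkaline release).
#'
#' @param composition A [glycan_composition()].
#' @param label `"none"` or `"two_AB"`.
#' @param state `"intact"` or `"mono_deacetylated"` (requires NeuAc >= 1).
#' @param short_name Display name, e.g. `"GalGalNAc"`.
#' @return An object of class `glycan_species`.
#' @export
glycan_species <- function(composition, label = c("two_AB", "none"),
                           state = c("intact", "mono_deacetylated"),
                           short_name = format(composition)) {
  label <- match.arg(label)
  state <- match.arg(state)
  if (!is_glycan_composition(composition))
    stop("composition must be a glycan_composition")
  if (state == "mono_deacetylated" && composition[["NeuAc"]] < 1)
    stop("mono_deacetylated species requires NeuAc count >= 1")
  structure(list(composition = composition, label = label, state = state,
                 short_name = short_name), class = "glycan_species")
}

#' m/z of a 2-AB labeled released glycan
#'
#' `(free reducing mass + 120.068748 - acetyl if mono-deacetylated +
#' charge x proton) / charge`.
#'
#' @param species A [glycan_species()] with `label = "two_AB"`.
#' @param charge Positive integer charge state.
#' @return m/z.
#' @export
#' @examples
#' core1 <- glycan_species(glycan_composition(HexNAc = 1, Hex = 1),
#'                         short_name = "GalGalNAc")
#' labeled_glycan_mz(core1)  # 504.22
labeled_glycan_mz <- function(species, charge = 1L) {
  mt <- mass_table()$constants
  if (!inherits(species, "glycan_species")) stop("species must be a glycan_species")
  if (species$label != "two_AB") stop("labeled_glycan_mz requires a 2-AB labeled species")
  if (length(charge) != 1L || charge < 1) stop("charge must be >= 1")
  m <- glycan_mass(species$composition, "free_reducing") + mt[["two_ab_net"]]
  if (species$state == "mono_deacetylated") m <- m - mt[["acetyl"]]
  (m + charge * mt[["proton"]]) / charge
}

#' Glycopeptide precursor m/z
#'
#' @param sequence Peptide sequence (one-letter codes).
#' @param site_glycans Named list of [glycan_composition()] objects; names are
#'   1-based positions within `sequence`, each an S or T residue. May be
#'   empty for a bare peptide.
#' @param charge Positive integer charge state.
#' @param mods Optional variable modifications, as for [peptide_mass()].
#' @return Precursor m/z.
#' @export
#' @examples
#' glycopeptide_mz("SRLPGP",
#'   list(`1` = glycan_composition(HexNAc = 1, Hex = 1)), charge = 1)
glycopeptide_mz <- function(sequence, site_glycans = list(), charge = 1L,
                            mods = NULL) {
  mt <- mass_table()$constants
  if (length(charge) != 1L || charge < 1) stop("charge must be >= 1")
  gmass <- 0
  if (length(site_glycans)) {
    pos <- as.integer(names(site_glycans))
    if (anyNA(pos)) stop("site_glycans must be named by 1-based positions")
    letters <- strsplit(sequence, "")[[1]]
    if (any(pos < 1 | pos > length(letters)))
      stop("glycan position outside the sequence")
    if (!all(letters[pos] %in% c("S", "T")))
      stop(sprintf("glycan on non-S/T residue at position %d",
                   pos[!letters[pos] %in% c("S", "T")][1]))
    gmass <- sum(vapply(site_glycans, glycan_mass, numeric(1), form = "residue"))
  }
  (peptide_mass(sequence, mods) + gmass + charge * mt[["proton"]]) / charge
}

#' Signed parts-per-million mass error
#'
#' @param observed,theoretical m/z values; `theoretical` must be positive.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  1e6 * (observed - theoretical) / theoretical
}
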