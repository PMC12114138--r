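# Shared fixtures and independent oracles.

core1 <- glycan_composition(HexNAc = 1, Hex = 1)
core1_neuac1 <- glycan_composition(HexNAc = 1, Hex = 1, NeuAc = 1)
core1_neuac2 <- glycan_composition(HexNAc = 1, Hex = 1, NeuAc = 2)

ctp <- fsh_ctp_preset()

# Brute-force digestion oracle: enumerate every substring and keep those
# satisfying the boundary rules. Independent of digest_operator's recursion
# over cleavage-site indices.
oracle_digest <- function(sequence, sites, max_missed, offset = 1L,
                          mode = "specific") {
  n <- nchar(sequence)
  prot_end <- offset + n - 1L
  rows <- list()
  for (s in seq(offset, prot_end)) {
    if (!s %in% sites) next
    for (e in seq(s, prot_end)) {
      if (mode == "specific" && e != prot_end && !(e + 1L) %in% sites) next
      mc <- sum(sites > s & sites <= e)
      if (mc > max_missed) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(sequence, s - offset + 1L, e - offset + 1L),
        start = s, end = e, missed_cleavages = mc)
    }
  }
  if (!length(rows))
    return(data.frame(sequence = character(), start = integer(),
                      end = integer(), missed_cleavages = integer()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), ]
}

# random protein with guaranteed S/T content
random_protein <- function(n, alphabet = c("S", "T", "A", "P", "L", "G", "K")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random non-empty subset of candidate sites (safe for length-1 vectors)
pick_sites <- function(st) {
  sort(st[sample.int(length(st), sample.int(length(st), 1))])
}

make_gp <- function(sequence, start, sites, comp = core1) {
  glycopeptide(sequence, start,
               stats::setNames(rep(list(comp), length(sites)), sites))
}

# noiseless full-ladder spectrum for a glycopeptide (EThcD by default)
perfect_spectrum <- function(gp, mode = "EThcD", charge = 2L, id = "perfect") {
  ions <- theoretical_ions(gp, mode = mode)
  spectrum(gp_precursor_mz(gp, charge), charge,
           data.frame(mz = ions$mz, intensity = 100), id = id)
}
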