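## In-silico OpeRATOR + sialidase digestion. OpeRATOR cleaves the peptide
## backbone immediately N-terminal to an O-glycosylated (core 1/3) Ser/Thr,
## so every true product starts with a glycosylated S/T. Glycosites are an
## input (occupancy is sample-dependent), not predicted.

#' Remove sialic acids from a glycan composition
#'
#' Models exhaustive sialidase treatment: the NeuAc count is set to zero and
#' all other counts are unchanged. A composition that becomes empty (e.g. a
#' free NeuAc peeling product) is invalid downstream; `NULL` is returned with
#' a warning.
#'
#' @param comp A [glycan_composition()], or a list of them (empties dropped).
#' @return The desialylated composition(s).
#' @export
#' @examples
#' apply_sialidase(glycan_composition(HexNAc = 1, Hex = 1, NeuAc = 2))
apply_sialidase <- function(comp) {
  if (is.list(comp) && !is_glycan_composition(comp)) {
    out <- lapply(comp, apply_sialidase)
    out <- out[!vapply(out, is.null, logical(1))]
    return(out[!duplicated(vapply(out, format, character(1)))])
  }
  if (!is_glycan_composition(comp)) stop("comp must be a glycan_composition")
  counts <- setNames(as.integer(comp), names(comp))
  counts[["NeuAc"]] <- 0L
  if (sum(counts) == 0L) {
    warning("desialylation left an empty composition")
    return(NULL)
  }
  do.call(glycan_composition, as.list(counts))
}

#' Glycopeptide constructor
#'
#' A peptide span in protein coordinates plus a site -> glycan map.
#'
#' @param sequence Peptide sequence.
#' @param start 1-based protein coordinate of the first residue (the protein
#'   numbering may carry an offset, e.g. the CTP starts at 112).
#' @param site_glycans Named list of [glycan_composition()]; names are
#'   protein positions of glycosylated S/T residues inside the span.
#' @param missed_cleavages Optional integer bookkeeping from the digest.
#' @return An object of class `glycopeptide`.
#' @export
glycopeptide <- function(sequence, start, site_glycans = list(),
                         missed_cleavages = NA_integer_) {
  n <- nchar(sequence)
  end <- start + n - 1L
  if (length(site_glycans)) {
    pos <- as.integer(names(site_glycans))
    if (anyNA(pos) || any(pos < start | pos > end))
      stop("glycan positions must be protein coordinates inside the span")
    letters <- strsplit(sequence, "")[[1]]
    if (!all(letters[pos - start + 1L] %in% c("S", "T")))
      stop("glycan positions must be S or T residues")
    if (!all(vapply(site_glycans, is_glycan_composition, logical(1))))
      stop("site_glycans must contain glycan_composition objects")
    site_glycans <- site_glycans[order(pos)]
  }
  structure(list(sequence = sequence, start = as.integer(start),
                 end = as.integer(end), site_glycans = site_glycans,
                 missed_cleavages = as.integer(missed_cleavages)),
            class = "glycopeptide")
}

#' @export
format.glycopeptide <- function(x, ...) {
  sites <- if (length(x$site_glycans)) {
    paste(vapply(seq_along(x$site_glycans), function(i) {
      paste0(names(x$site_glycans)[i], ":", format(x$site_glycans[[i]]))
    }, character(1)), collapse = ",")
  } else "none"
  sprintf("%s (%d-%d) [%s]", x$sequence, x$start, x$end, sites)
}

#' @export
print.glycopeptide <- function(x, ...) {
  cat("<glycopeptide>", format(x), "\n"); invisible(x)
}

#' Precursor m/z of a glycopeptide object
#'
#' @param gp A [glycopeptide()].
#' @param charge Positive integer charge state.
#' @return m/z.
#' @export
gp_precursor_mz <- function(gp, charge = 2L) {
  local <- as.integer(names(gp$site_glycans)) - gp$start + 1L
  sg <- gp$site_glycans
  names(sg) <- local
  glycopeptide_mz(gp$sequence, sg, charge)
}

## local (1-based within peptide) positions of the glycosylated sites
gp_local_sites <- function(gp) as.integer(names(gp$site_glycans)) - gp$start + 1L

#' In-silico OpeRATOR digestion
#'
#' Cleaves a protein immediately N-terminal to each glycosite, with missed
#' cleavages. In `"specific"` mode every product starts at a glycosite and
#' ends one residue before another glycosite (or at the protein C-terminus),
#' skipping at most `max_missed` internal glycosites. `"semi_specific"` mode
#' additionally allows ragged C-termini: any end position such that the
#' number of internal glycosites in the span stays within `max_missed`.
#'
#' The protein-N-terminal leftover preceding the first glycosite (e.g. SS
#' 112-113 for the CTP) is emitted flagged `is_glycopeptide = FALSE` rather
#' than silently dropped.
#'
#' @param sequence Protein sequence.
#' @param glycosites Integer protein positions (S/T) assumed glycosylated;
#'   use [all_st_sites()] to treat every S/T as a candidate.
#' @param max_missed Maximum internal (non-N-terminal) glycosites per span.
#' @param mode `"specific"` or `"semi_specific"`.
#' @param offset Protein coordinate of the first residue (default 1; the CTP
#'   preset uses 112).
#' @return A data.frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`, `is_glycopeptide`, duplicate-free and sorted by
#'   `(start, end)`.
#' @export
#' @examples
#' digest_operator(fsh_ctp_preset()$sequence, c(126, 134),
#'                 max_missed = 0, offset = 112)
digest_operator <- function(sequence, glycosites, max_missed = 3L,
                            mode = c("specific", "semi_specific"),
                            offset = 1L) {
  mode <- match.arg(mode)
  n <- nchar(sequence)
  letters <- strsplit(sequence, "")[[1]]
  prot_end <- offset + n - 1L
  glycosites <- sort(unique(as.integer(glycosites)))
  if (length(glycosites)) {
    if (any(glycosites < offset | glycosites > prot_end))
      stop("glycosite outside the protein")
    bad <- glycosites[!letters[glycosites - offset + 1L] %in% c("S", "T")]
    if (length(bad))
      stop(sprintf("glycosite at non-S/T position %d", bad[1]))
  }
  if (length(glycosites) == 0L)
    return(data.frame(sequence = character(), start = integer(),
                      end = integer(), missed_cleavages = integer(),
                      is_glycopeptide = logical()))
  rows <- list()
  add <- function(s, e, mc, glyco) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sequence = substr(sequence, s - offset + 1L, e - offset + 1L),
      start = s, end = e, missed_cleavages = mc, is_glycopeptide = glyco)
  }
  for (i in seq_along(glycosites)) {
    s <- glycosites[i]
    later <- glycosites[glycosites > s]
    if (mode == "specific") {
      ends <- c(later - 1L, prot_end)
      missed <- seq_along(ends) - 1L
      keep <- missed <= max_missed
      # drop a duplicate when the last glycosite's "next boundary" span
      # coincides with the protein end
      for (j in which(keep)) add(s, ends[j], missed[j], TRUE)
    } else {
      for (e in s:prot_end) {
        mc <- sum(later <= e)
        if (mc <= max_missed) add(s, e, mc, TRUE)
      }
    }
  }
  if (glycosites[1] > offset)
    add(offset, glycosites[1] - 1L, 0L, FALSE)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("start", "end")]), , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' All S/T positions of a protein
#'
#' Convenience candidate-site mode: OpeRATOR only cleaves at occupied sites,
#' which is sample-dependent, so the default pipelines take known or
#' hypothesized sites; this helper enumerates every possibility.
#'
#' @param sequence Protein sequence.
#' @param offset Protein numbering offset.
#' @return Integer vector of S/T protein positions.
#' @export
all_st_sites <- function(sequence, offset = 1L) {
  which(strsplit(sequence, "")[[1]] %in% c("S", "T")) + offset - 1L
}

#' Enumerate glycoforms of a digested span
#'
#' Assigns an allowed composition to every glycosite inside the span (the
#' N-terminal site of an OpeRATOR product is always glycosylated), yielding
#' `|allowed| ^ n_sites` glycopeptides. With `internal_optional = TRUE`,
#' non-N-terminal sites may additionally be unoccupied, which is what a
#' closed search over missed-cleavage products requires (an uncut internal
#' S/T need not carry a glycan).
#'
#' @param span One row of [digest_operator()] output (or a list with
#'   `sequence`, `start`, `end`, and optionally `missed_cleavages`).
#' @param glycosites Integer protein positions of candidate glycosites.
#' @param allowed List of [glycan_composition()] objects.
#' @param internal_optional Allow unoccupied internal sites.
#' @return A list of [glycopeptide()] objects.
#' @export
enumerate_glycoforms <- function(span, glycosites, allowed,
                                 internal_optional = FALSE) {
  if (is.data.frame(span)) span <- as.list(span[1, ])
  if (!length(allowed)) stop("allowed glycan list must be non-empty")
  if (is_glycan_composition(allowed)) allowed <- list(allowed)
  sites <- sort(glycosites[glycosites >= span$start & glycosites <= span$end])
  if (!length(sites)) stop("span contains no glycosite")
  choices <- lapply(sites, function(p) {
    idx <- seq_along(allowed)
    if (internal_optional && p != span$start) c(0L, idx) else idx
  })
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    pick <- as.integer(grid[r, ])
    keep <- pick > 0L
    sg <- setNames(lapply(pick[keep], function(k) allowed[[k]]),
                   sites[keep])
    # missed cleavages = occupied internal sites: an unoccupied S/T is not
    # an OpeRATOR substrate, hence not a missed cleavage site
    out[[r]] <- glycopeptide(span$sequence, span$start, sg,
                             sum(sites[keep] != span$start))
  }
  out
}
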