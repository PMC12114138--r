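## File formats: FASTA in (via Biostrings), MGF in/out (hand-rolled; the
## dialect is BEGIN IONS / TITLE / PEPMASS / CHARGE / mz-intensity rows),
## and CSV/TSV report writers with a provenance header.

#' Read protein records from FASTA
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `description`, `sequence`
#'   (uppercased), in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nm <- names(set)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  ok_letters <- names(mass_table()$residues)
  for (i in seq_along(seqs)) {
    letters <- strsplit(seqs[i], "")[[1]]
    bad <- which(!letters %in% ok_letters)
    if (length(bad))
      stop(sprintf("record %d ('%s'): illegal residue '%s' at position %d",
                   i, sub(" .*", "", nm[i]), letters[bad[1]], bad[1]))
  }
  data.frame(id = sub(" .*", "", nm),
             description = sub("^\\S+\\s*", "", nm),
             sequence = unname(seqs))
}

#' Write spectra to MGF
#'
#' Peak m/z values are written at 6 decimals so that a write/read round trip
#' is bit-exact on the supported fields.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp$id),
                 sprintf("PEPMASS=%.6f", sp$precursor_mz),
                 sprintf("CHARGE=%d+", sp$precursor_charge),
                 sprintf("%.6f %.4f", sp$peaks$mz, sp$peaks$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read spectra from MGF
#'
#' Supports TITLE, PEPMASS, CHARGE (`2+` style) and peak rows. A block
#' without PEPMASS, or an empty BEGIN/END block, is skipped with a warning.
#'
#' @param path MGF file.
#' @return List of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) stop("unbalanced BEGIN/END IONS blocks")
  out <- list()
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    if (length(block) == 0L || ends[k] - starts[k] <= 1L) {
      warning("empty spectrum block skipped (block ", k, ")")
      next
    }
    is_hdr <- grepl("=", block, fixed = TRUE)
    hdr <- block[is_hdr]
    key <- sub("=.*", "", hdr)
    val <- sub("^[^=]*=", "", hdr)
    if (!"PEPMASS" %in% key) {
      warning("spectrum block without PEPMASS skipped (block ", k, ")")
      next
    }
    pepmass <- as.numeric(strsplit(val[key == "PEPMASS"][1], "\\s+")[[1]][1])
    charge <- if ("CHARGE" %in% key)
      as.integer(sub("\\+$", "", val[key == "CHARGE"][1])) else 1L
    id <- if ("TITLE" %in% key) val[key == "TITLE"][1]
          else sprintf("spectrum_%d", k)
    pk_lines <- block[!is_hdr & nzchar(trimws(block))]
    peaks <- if (length(pk_lines)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk_lines), "\\s+"),
                                 function(x) as.numeric(x[1:2])))
      data.frame(mz = m[, 1], intensity = m[, 2])
    } else data.frame(mz = numeric(), intensity = numeric())
    out[[length(out) + 1L]] <- spectrum(pepmass, charge, peaks, id = id)
  }
  out
}

## report writer with a provenance header (config values used)
write_report_csv <- function(df, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(config)) {
    writeLines(sprintf("# %s=%s", names(config),
                       vapply(config, function(x) paste(x, collapse = ","),
                              character(1))), con)
  }
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_report_csv <- function(path) read.csv(path, comment.char = "#")
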