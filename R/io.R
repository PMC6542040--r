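# File formats: substrate FASTA (accession|symbol|source headers) and a
# minimal MGF dialect (BEGIN IONS / END IONS, PEPMASS + CHARGE honored).
# No R mass-spectrometry IO package is available in the deployment
# environment, so the MGF reader/writer is implemented here; it covers only
# the centroided peak-list dialect this pipeline emits and consumes.

#' Read a substrate protein database FASTA
#'
#' Headers follow `>accession|symbol|source free text`, where `source` is a
#' comma-separated subset of `{MEROPS, SignalP}` recording how the protein
#' entered the restricted search space (known matrix-protease substrate vs
#' predicted secreted protein).
#'
#' @param path FASTA file path.
#' @return `data.frame` with columns `accession`, `symbol`, `source`,
#'   `description`, `sequence`.
#' @export
read_substrate_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  headers <- names(aa)
  first <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  parts <- strsplit(first, "|", fixed = TRUE)
  acc <- vapply(parts, `[`, "", 1L)
  sym <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, "")
  src <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else NA_character_, "")
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(aa))
  bad <- !grepl(sprintf("^[%s]+$", paste(names(RESIDUE_MASSES), collapse = "")), seqs)
  if (any(bad))
    stop("invalid residue characters in record(s): ",
         paste(acc[bad], collapse = ", "), call. = FALSE)
  data.frame(accession = acc, symbol = sym, source = src,
             description = desc, sequence = seqs, stringsAsFactors = FALSE)
}

#' Write a substrate protein database FASTA
#' @param db `data.frame` as returned by [read_substrate_fasta()].
#' @param path Output path.
#' @export
write_substrate_fasta <- function(db, path) {
  hdr <- sprintf(">%s|%s|%s%s", db$accession, db$symbol, db$source,
                 ifelse(nzchar(db$description), paste0(" ", db$description), ""))
  lines <- character(0)
  for (i in seq_len(nrow(db))) {
    chunks <- substring(db$sequence[i],
                        seq(1L, nchar(db$sequence[i]), 60L),
                        pmin(seq(1L, nchar(db$sequence[i]), 60L) + 59L,
                             nchar(db$sequence[i])))
    lines <- c(lines, hdr[i], chunks)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an MGF peak list
#'
#' Parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS, CHARGE, RTINSECONDS
#' headers. Precursors are converted to the charge-reduced singly protonated
#' mass: `MH+ = z * mz - (z - 1) * proton`. A missing CHARGE is read as 1+.
#'
#' @param path MGF file path.
#' @return List of spectra; each is a list with `title`, `precursor_mh`
#'   (charge-reduced MH+, Da), `rt` (seconds or NA) and a two-column matrix
#'   `peaks` (`mz`, `intensity`) sorted by m/z.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends))
    stop("malformed MGF: unbalanced BEGIN/END IONS", call. = FALSE)
  lapply(seq_along(starts), function(k) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    is_hdr <- grepl("=", block, fixed = TRUE)
    hdr <- block[is_hdr]
    keys <- toupper(sub("=.*$", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    getv <- function(key) if (key %in% keys) vals[match(key, keys)] else NA_character_
    mz_line <- getv("PEPMASS")
    pepmass <- as.numeric(strsplit(trimws(mz_line), "\\s+")[[1L]][1L])
    ch <- getv("CHARGE")
    z <- if (is.na(ch)) 1L else as.integer(gsub("[^0-9]", "", ch))
    peak_lines <- block[!is_hdr & nzchar(trimws(block))]
    peaks <- if (length(peak_lines)) {
      m <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "\\s+"),
                                 function(x) as.numeric(x[1:2])))
      colnames(m) <- c("mz", "intensity")
      m[order(m[, "mz"]), , drop = FALSE]
    } else {
      matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("mz", "intensity")))
    }
    list(title = getv("TITLE"),
         precursor_mh = z * pepmass - (z - 1L) * PROTON_MASS,
         rt = as.numeric(getv("RTINSECONDS")),
         peaks = peaks)
  })
}

#' Write spectra to MGF
#' @param spectra List of spectra as produced by [read_mgf()] or
#'   [synthesize_spectra()] (charge-reduced MH+ precursors, written as 1+).
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", sp$title), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mh), con)
    writeLines("CHARGE=1+", con)
    if (!is.null(sp$rt) && !is.na(sp$rt))
      writeLines(sprintf("RTINSECONDS=%.2f", sp$rt), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.6f %.4f", sp$peaks[, 1L], sp$peaks[, 2L]), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
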