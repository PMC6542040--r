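# No-enzyme peptide-spectrum identification against a substrate-restricted
# database with random-decoy FDR estimation.
#
# Candidates are all protein substrings whose theoretical charge-reduced MH+
# lies within the precursor tolerance; per-protein cumulative residue-mass
# prefix arrays make any substring mass an O(1) difference and turn candidate
# lookup into a binary-search window per start position.

#' Build a searchable index over a substrate database
#'
#' @param db Substrate database from [read_substrate_fasta()] or
#'   [build_toy_substrate_db()].
#' @param mods Residue mass table; the default applies fixed
#'   carbamidomethyl-C.
#' @return Object of class `substrate_index`: the database plus per-protein
#'   strictly increasing prefix mass arrays (first entry 0).
#' @export
build_index <- function(db, mods = residue_table()) {
  if (nrow(db) == 0L) stop("empty substrate database", call. = FALSE)
  if (anyDuplicated(db$accession))
    stop("duplicate accession(s): ",
         paste(unique(db$accession[duplicated(db$accession)]), collapse = ", "),
         call. = FALSE)
  prefixes <- lapply(db$sequence, function(s) {
    chars <- .check_sequence(s)
    c(0, cumsum(unname(mods[chars])))
  })
  structure(list(db = db, prefixes = prefixes, mods = mods),
            class = "substrate_index")
}

#' Substring residue-sum mass from the index
#' @param index `substrate_index`.
#' @param protein Protein row index.
#' @param start,end 1-based inclusive residue coordinates.
#' @return Residue-sum mass (Da).
#' @export
substring_mass <- function(index, protein, start, end) {
  p <- index$prefixes[[protein]]
  p[end + 1L] - p[start]
}

#' Enumerate no-enzyme candidate peptides for a precursor
#'
#' All (protein, start, end) substrings whose theoretical MH+ lies within
#' `ppm` of the precursor and whose length is within `len_bounds`, merged by
#' sequence with multi-protein provenance.
#'
#' @param precursor_mh Charge-reduced precursor MH+ (Da).
#' @param index `substrate_index`.
#' @param ppm Precursor tolerance (default 6).
#' @param len_bounds Peptide length bounds, inclusive (default `c(6, 80)`).
#' @return `data.table` with `sequence`, `accessions` (comma-joined),
#'   `protein`, `start`, `end`, `theoretical_mh`, `ppm` — one row per unique
#'   sequence (first-occurrence coordinates); empty if no candidate.
#' @export
candidate_peptides <- function(precursor_mh, index, ppm = 6,
                               len_bounds = c(6, 80)) {
  if (precursor_mh <= 0) stop("precursor_mh must be positive", call. = FALSE)
  t_lo <- precursor_mh * (1 - ppm / 1e6) - WATER_MASS - PROTON_MASS
  t_hi <- precursor_mh * (1 + ppm / 1e6) - WATER_MASS - PROTON_MASS
  hits <- list()
  for (pi in seq_along(index$prefixes)) {
    p <- index$prefixes[[pi]]
    L <- length(p) - 1L
    starts <- seq_len(L)
    # k = end + 1 indices with substring residue sum in [t_lo, t_hi];
    # the prefix array is strictly increasing, so both bounds are one
    # vectorized binary search
    k_lo <- pmax(findInterval(p[starts] + t_lo, p, left.open = TRUE) + 1L,
                 starts + len_bounds[1L])
    k_hi <- pmin(findInterval(p[starts] + t_hi, p),
                 starts + len_bounds[2L], L + 1L)
    open <- which(k_lo <= k_hi)
    for (i in open) {
      for (k in k_lo[i]:k_hi[i]) {
        end <- k - 1L
        mh <- p[k] - p[i] + WATER_MASS + PROTON_MASS
        hits[[length(hits) + 1L]] <- data.table::data.table(
          sequence = substr(index$db$sequence[pi], i, end),
          accessions = index$db$accession[pi],
          protein = pi, start = i, end = end,
          theoretical_mh = mh,
          ppm = ppm_error(precursor_mh, mh))
      }
    }
  }
  if (!length(hits))
    return(data.table::data.table(sequence = character(0),
                                  accessions = character(0),
                                  protein = integer(0), start = integer(0),
                                  end = integer(0), theoretical_mh = numeric(0),
                                  ppm = numeric(0)))
  all_hits <- data.table::rbindlist(hits)
  merged <- all_hits[, .(accessions = paste(unique(accessions), collapse = ","),
                         protein = protein[1L], start = start[1L], end = end[1L],
                         theoretical_mh = theoretical_mh[1L], ppm = ppm[1L]),
                     by = sequence]
  merged[]
}

#' Score a candidate against a fragment spectrum
#'
#' Greedy one-to-one matching of theoretical b/y ions to the nearest
#' unclaimed spectrum peak within `product_ppm`. The score is a
#' hyperscore-style surrogate,
#' `S = Nb * log2(1 + Ib) + Ny * log2(1 + Iy)`, where Nb/Ny are matched ion
#' counts and Ib/Iy the summed matched intensities relative to the spectrum's
#' total intensity.
#'
#' @param spectrum Spectrum in the [read_mgf()] layout.
#' @param sequence Candidate peptide sequence.
#' @param mods Residue mass table.
#' @param product_ppm Product ion tolerance (default 12).
#' @return List: `score`, `n_b`, `n_y`, `max_product_ppm` (NA when nothing
#'   matched).
#' @export
score_psm <- function(spectrum, sequence, mods = residue_table(),
                      product_ppm = 12) {
  lad <- fragment_ladder(sequence, mods)
  peaks <- spectrum$peaks
  total <- sum(peaks[, "intensity"])
  used <- logical(nrow(peaks))
  match_series <- function(theo) {
    n <- 0L; rel <- 0; max_ppm <- 0
    for (tm in theo) {
      tol <- product_ppm * tm / 1e6
      cand <- which(!used & abs(peaks[, "mz"] - tm) <= tol)
      if (!length(cand)) next
      best <- cand[which.min(abs(peaks[cand, "mz"] - tm))]
      used[best] <<- TRUE
      n <- n + 1L
      rel <- rel + peaks[best, "intensity"] / total
      max_ppm <- max(max_ppm, abs(ppm_error(peaks[best, "mz"], tm)))
    }
    list(n = n, rel = rel, max_ppm = max_ppm)
  }
  b <- match_series(lad$b)
  y <- match_series(lad$y)
  score <- b$n * log2(1 + b$rel) + y$n * log2(1 + y$rel)
  list(score = score, n_b = b$n, n_y = y$n,
       max_product_ppm = if (b$n + y$n > 0L) max(b$max_ppm, y$max_ppm) else NA_real_)
}

.best_match <- function(spectrum, index, precursor_ppm, product_ppm, len_bounds) {
  cand <- candidate_peptides(spectrum$precursor_mh, index, precursor_ppm,
                             len_bounds)
  if (!nrow(cand)) return(NULL)
  scores <- lapply(cand$sequence, function(s)
    score_psm(spectrum, s, index$mods, product_ppm))
  sc <- vapply(scores, `[[`, 0, "score")
  # ties: smaller |precursor ppm|, then lexicographic sequence
  ord <- order(-sc, abs(cand$ppm), cand$sequence)
  i <- ord[1L]
  data.table::data.table(
    title = spectrum$title,
    sequence = cand$sequence[i],
    accessions = cand$accessions[i],
    protein = cand$protein[i], start = cand$start[i], end = cand$end[i],
    theoretical_mh = cand$theoretical_mh[i],
    precursor_mh = spectrum$precursor_mh,
    precursor_ppm = cand$ppm[i],
    max_product_ppm = scores[[i]]$max_product_ppm,
    n_b = scores[[i]]$n_b, n_y = scores[[i]]$n_y,
    score = sc[i])
}

#' Shuffle-decoy database
#'
#' Length- and composition-preserving per-protein residue shuffle with a
#' fixed seed. Accessions are prefixed `DECOY_`.
#'
#' @param db Substrate database.
#' @param seed Shuffle seed.
#' @return Decoy database `data.frame`.
#' @export
decoy_db <- function(db, seed = 7) {
  with_seed(seed, {
    out <- db
    out$sequence <- vapply(db$sequence, function(s) {
      paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
    }, "", USE.NAMES = FALSE)
    out$accession <- paste0("DECOY_", db$accession)
    out
  })
}

#' Target-decoy search over a spectrum set
#'
#' Searches every spectrum against the target database and a seeded
#' shuffle-decoy copy, retaining the best-scoring match per spectrum on each
#' side (peptide-level competition within each database).
#'
#' @param spectra Spectrum list ([read_mgf()] layout).
#' @param index Target `substrate_index`.
#' @param precursor_ppm,product_ppm Match tolerances (defaults 6 and 12).
#' @param len_bounds Candidate length bounds.
#' @param decoy_seed Seed for the decoy shuffle.
#' @return List with `target` and `decoy` best-match `data.table`s.
#' @export
decoy_search <- function(spectra, index, precursor_ppm = 6, product_ppm = 12,
                         len_bounds = c(6, 80), decoy_seed = 7) {
  dindex <- build_index(decoy_db(index$db, decoy_seed), index$mods)
  run <- function(idx) {
    rows <- lapply(spectra, .best_match, index = idx,
                   precursor_ppm = precursor_ppm, product_ppm = product_ppm,
                   len_bounds = len_bounds)
    data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)])
  }
  list(target = run(index), decoy = run(dindex))
}

#' Random-decoy FDR thresholding
#'
#' For a score threshold s the estimated FDR is
#' `#{decoy >= s} / #{target >= s}`; each target match is assigned the
#' q value `min` of that ratio over all thresholds at or below its own score,
#' and accepted if `q <= fdr`.
#'
#' @param target,decoy Best-match tables from [decoy_search()].
#' @param fdr Nominal FDR (default 0.10).
#' @return The target table with added `q_value` and `accepted` columns,
#'   sorted by descending score.
#' @export
fdr_threshold <- function(target, decoy, fdr = 0.10) {
  if (!nrow(target)) {
    out <- data.table::copy(target)
    out[, `:=`(q_value = numeric(0), accepted = logical(0))]
    return(out[])
  }
  out <- data.table::copy(target)[order(-score)]
  dscores <- sort(decoy$score, decreasing = TRUE)
  n_dec <- vapply(out$score, function(s) sum(dscores >= s), 0L)
  fdp <- n_dec / seq_len(nrow(out))
  out[, q_value := rev(cummin(rev(pmin(fdp, 1))))]
  out[, accepted := q_value <= fdr]
  out[]
}

#' Annotate an accepted match with database provenance
#'
#' @param match One-row match (from [fdr_threshold()] output).
#' @param index Target `substrate_index`.
#' @return One-row `data.frame` mirroring a reported identification: peptide
#'   sequence, parent protein name/symbol/accession, source tag, theoretical
#'   peptide (residue-sum) mass, measured precursor, ppm errors, score and
#'   q value, plus 1-based start/end coordinates.
#' @export
annotate_match <- function(match, index) {
  prot <- index$db[match$protein, ]
  stopifnot(substr(prot$sequence, match$start, match$end) == match$sequence)
  data.frame(
    sequence = match$sequence,
    protein_name = sub(" \\(synthetic excerpt\\)$", "", prot$description),
    symbol = prot$symbol,
    accession = match$accessions,
    source = prot$source,
    start = match$start, end = match$end,
    peptide_mass = match$theoretical_mh - WATER_MASS - PROTON_MASS,
    precursor_mass = match$precursor_mh,
    precursor_ppm = match$precursor_ppm,
    max_product_ppm = match$max_product_ppm,
    score = match$score,
    q_value = if ("q_value" %in% names(match)) match$q_value else NA_real_,
    stringsAsFactors = FALSE)
}
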