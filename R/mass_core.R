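# Monoisotopic peptide mass arithmetic: residue sums, fixed modifications,
# ppm errors and singly protonated b/y fragment ladders.

#' Physical constants (monoisotopic, Da)
#' @name mass-constants
#' @keywords internal
NULL

PROTON_MASS <- 1.007276
WATER_MASS  <- 18.010565
CARBAMIDOMETHYL_DELTA <- 57.02146

# Monoisotopic residue masses (peptide-bond residues, i.e. amino acid - water).
RESIDUE_MASSES <- c(
  G = 57.021464,  A = 71.037114,  S = 87.032028,  P = 97.052764,
  V = 99.068414,  T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Residue mass table with fixed modifications
#'
#' Returns the monoisotopic residue mass lookup used throughout the package,
#' with fixed modification deltas folded into the affected residues. The
#' default applies carbamidomethylation (+57.02146 Da) to cysteine, the
#' convention for iodoacetamide-alkylated samples; identification and all
#' theoretical-mass computations assume it is always on.
#'
#' @param fixed_mods Named numeric vector of delta masses (Da) keyed by the
#'   one-letter residue they modify. Use `character(0)`-named empty numeric
#'   for unmodified masses.
#' @return Named numeric vector over the 20 standard residues.
#' @export
#' @examples
#' residue_table()[["C"]]                 # carbamidomethylated Cys
#' residue_table(fixed_mods = numeric())[["C"]]
residue_table <- function(fixed_mods = c(C = CARBAMIDOMETHYL_DELTA)) {
  tab <- RESIDUE_MASSES
  if (length(fixed_mods)) {
    stopifnot(!is.null(names(fixed_mods)), all(names(fixed_mods) %in% names(tab)))
    tab[names(fixed_mods)] <- tab[names(fixed_mods)] + fixed_mods
  }
  tab
}

.check_sequence <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("peptide sequence must be a single non-empty string", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), names(RESIDUE_MASSES))
  if (length(bad))
    stop(sprintf("invalid residue character(s) in sequence: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  chars
}

#' Sum of monoisotopic residue masses
#'
#' Residue-sum mass of a peptide: the sum of monoisotopic residue masses plus
#' any fixed-modification deltas on matching residues. No water or proton term
#' is added; see [mh_plus()] for the singly protonated species.
#'
#' @param seq Peptide sequence, uppercase one-letter code.
#' @param mods Residue mass table from [residue_table()].
#' @return Mass in Da.
#' @export
#' @examples
#' residue_mass_sum("LPFKNL")   # 712.4272
residue_mass_sum <- function(seq, mods = residue_table()) {
  chars <- .check_sequence(seq)
  sum(mods[chars])
}

#' Charge-reduced protonated mass (MH+)
#'
#' Converts a residue-sum mass to the singly protonated peptide mass by adding
#' one water (peptide termini) and one proton.
#'
#' @param residue_sum Residue-sum mass in Da (positive).
#' @return MH+ in Da.
#' @export
mh_plus <- function(residue_sum) {
  if (any(!is.finite(residue_sum)) || any(residue_sum <= 0))
    stop("residue_sum must be positive and finite", call. = FALSE)
  residue_sum + WATER_MASS + PROTON_MASS
}

#' Convenience: MH+ of a sequence
#' @inheritParams residue_mass_sum
#' @return MH+ in Da.
#' @export
peptide_mh <- function(seq, mods = residue_table()) {
  mh_plus(residue_mass_sum(seq, mods))
}

#' Signed parts-per-million mass error
#'
#' @param measured Measured mass (Da).
#' @param theoretical Theoretical mass (Da, positive).
#' @return Signed ppm error, `1e6 * (measured - theoretical) / theoretical`.
#' @export
ppm_error <- function(measured, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0))
    stop("theoretical mass must be positive", call. = FALSE)
  1e6 * (measured - theoretical) / theoretical
}

#' Singly protonated b/y fragment ladder
#'
#' Theoretical fragment ion masses for a peptide: b ions are prefix residue
#' sums plus a proton; y ions are suffix residue sums plus water and a proton.
#' Both series run over indices 1..n-1. The ladder identity
#' `b_i + y_{n-i} = MH+ + proton` holds for every index.
#'
#' @inheritParams residue_mass_sum
#' @return List with numeric vectors `b`, `y` (each length `nchar(seq) - 1`)
#'   and scalar `mh` (the peptide MH+).
#' @export
#' @examples
#' fragment_ladder("LPFKNL")$b[1]   # b1 = Leu residue + proton
fragment_ladder <- function(seq, mods = residue_table()) {
  chars <- .check_sequence(seq)
  n <- length(chars)
  if (n < 2L)
    stop("fragment ladder requires a peptide of length >= 2", call. = FALSE)
  masses <- unname(mods[chars])
  prefix <- cumsum(masses)
  b <- prefix[seq_len(n - 1L)] + PROTON_MASS
  suffix <- rev(cumsum(rev(masses)))
  y <- suffix[2:n] + WATER_MASS + PROTON_MASS
  y <- rev(y)  # y1 = C-terminal residue
  list(b = b, y = y, mh = prefix[n] + WATER_MASS + PROTON_MASS)
}
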