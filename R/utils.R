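# Shared helpers: deterministic seed derivation, partition comparison,
# plain-text table IO.

#' Derive a stage seed from a master seed
#'
#' Hashes a stage label into a 31-bit offset so each pipeline stage gets its
#' own reproducible RNG stream from one master seed. Re-running a single stage
#' in isolation with the same master seed reproduces its output.
#'
#' @param master Master seed (integer).
#' @param stage Stage label, e.g. `"simulate"`.
#' @return Integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(master) * 2654435761 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions, ~0 for independent ones. Used to compare recovered
#' feature clusters against the planted ground-truth partition.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return Numeric scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

read_tsv_dt <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
}

write_tsv_dt <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Path to a bundled example file
#' @param file File name under the package's `extdata` directory; empty lists
#'   the directory.
#' @return Absolute path.
#' @export
peptidome_example <- function(file = "") {
  system.file("extdata", file, package = "peptidome", mustWork = nzchar(file))
}
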