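# Independent oracle implementations and small fixture builders shared across
# the suite. Oracles deliberately use naive all-pairs / enumeration logic so
# they exercise none of the package's optimized code paths.

# Brute-force greedy clustering: same seeding rule as cluster_events (most
# intense unassigned event seeds; ties by mass, rt, drift, sample), but
# implemented as a naive repeated linear scan over all events.
oracle_cluster <- function(events, rt_tol = 2, drift_tol = 4, ppm_tol = 12) {
  ev <- as.data.frame(events)
  n <- nrow(ev)
  assigned <- rep(NA_integer_, n)
  feat <- 0L
  repeat {
    open <- which(is.na(assigned))
    if (!length(open)) break
    o <- open[order(-ev$intensity[open], ev$mass_da[open], ev$rt_min[open],
                    ev$drift_bin[open], ev$sample[open])]
    s <- o[1L]
    feat <- feat + 1L
    dm <- ppm_tol * ev$mass_da[s] / 1e6
    inbox <- open[abs(ev$mass_da[open] - ev$mass_da[s]) <= dm &
                    abs(ev$rt_min[open] - ev$rt_min[s]) <= rt_tol &
                    abs(ev$drift_bin[open] - ev$drift_bin[s]) <= drift_tol]
    if (length(inbox) > 1L) {
      d2 <- ((ev$rt_min[inbox] - ev$rt_min[s]) / rt_tol)^2 +
        ((ev$drift_bin[inbox] - ev$drift_bin[s]) / drift_tol)^2 +
        ((ev$mass_da[inbox] - ev$mass_da[s]) / dm)^2
      inbox <- inbox[order(d2, ev$mass_da[inbox], ev$rt_min[inbox])]
      inbox <- inbox[!duplicated(ev$sample[inbox])]
    }
    assigned[inbox] <- feat
  }
  assigned
}

# Brute-force BH step-up by the textbook definition: find the largest k with
# p_(k) <= k * alpha / m, reject all p <= p_(k); q_i is the smallest alpha at
# which i would be rejected, scanned on a fine grid of the attainable values.
oracle_bh_q <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    candidates <- vapply(seq_len(m), function(k) {
      # alpha at which rank-k rejection first covers p_i
      if (p[ord[k]] >= p[i]) p[ord[k]] * m / k else Inf
    }, 0)
    q[i] <- min(1, min(candidates))
  }
  q
}

# Exhaustive no-enzyme candidate enumeration over every substring.
oracle_candidates <- function(precursor_mh, db, ppm = 6, len_bounds = c(6, 80)) {
  out <- list()
  for (pi in seq_len(nrow(db))) {
    s <- db$sequence[pi]
    L <- nchar(s)
    for (i in seq_len(L)) {
      for (j in i:L) {
        len <- j - i + 1L
        if (len < len_bounds[1L] || len > len_bounds[2L]) next
        pep <- substr(s, i, j)
        mh <- peptide_mh(pep)
        if (abs(ppm_error(precursor_mh, mh)) <= ppm)
          out[[length(out) + 1L]] <- data.frame(sequence = pep,
                                                protein = pi, start = i,
                                                end = j)
      }
    }
  }
  if (!length(out)) return(data.frame(sequence = character(0)))
  do.call(rbind, out)
}

# Random peptide of given length (fixed alphabet, no RNG side effects left).
random_peptide <- function(n, seed = NULL) {
  aa <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q", "K",
          "E", "M", "H", "F", "R", "Y", "W")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# Tiny raw feature matrix + design for quantitation tests.
tiny_matrix <- function(n_feat = 20, n_per_group = 3, seed = 1) {
  design <- generate_design(n_per_group, doses = c(0, 40))
  set.seed(seed)
  m <- matrix(rlnorm(n_feat * nrow(design), log(5000), 0.4),
              nrow = n_feat,
              dimnames = list(sprintf("F%03d", seq_len(n_feat)), design$sample))
  attr(m, "transform") <- "raw"
  list(m = m, design = design)
}

# Default-world simulation shared by clustering/stats tests (cached per
# session to keep the suite fast).
default_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    db <- build_toy_substrate_db()
    design <- generate_design()
    truth <- generate_feature_truth(db, design, n_features = 2000, seed = 101)
    events <- emit_ion_events(truth, seed = 102)
    cache <<- list(db = db, design = design, truth = truth, events = events)
    cache
  }
})
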