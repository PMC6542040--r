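# Synthetic paired-fluid peptidome generator.
#
# Emulates the statistical structure the downstream analysis assumes: two
# fluids (serum, BALF) sampled from the same animals, three dose groups with
# n = 6 replicates, a fluid-overlap structure matching the ~29% BALF/serum
# detection-depth ratio, planted dose-responsive / exposure-exclusive / lost
# features, below-LOD censoring, and noisy b/y fragment spectra for features
# that correspond to real database subsequences.

DOSE_WEIGHT <- function(dose, top_dose) ifelse(dose <= 0, 0, dose / top_dose)

#' Generate a balanced paired study design
#'
#' Each animal contributes one serum and one BALF sample; dose groups are
#' balanced with `n_per_group` animals each.
#'
#' @param n_per_group Animals per dose group (>= 2; default 6).
#' @param doses Dose levels (default `c(0, 10, 40)` micrograms).
#' @param seed RNG seed (kept for interface symmetry; the design is
#'   deterministic).
#' @return `data.frame` with columns `sample`, `fluid`, `dose`, `replicate`,
#'   `animal`.
#' @export
generate_design <- function(n_per_group = 6, doses = c(0, 10, 40), seed = 1) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  grid <- expand.grid(replicate = seq_len(n_per_group), dose = doses,
                      fluid = c("serum", "BALF"), stringsAsFactors = FALSE)
  grid$animal <- paste0("a", match(paste(grid$dose, grid$replicate),
                                   unique(paste(grid$dose, grid$replicate))))
  grid$sample <- sprintf("%s_d%g_r%d", grid$fluid, grid$dose, grid$replicate)
  grid[, c("sample", "fluid", "dose", "replicate", "animal")]
}

.bivariate <- function(n, r) {
  x <- stats::rnorm(n)
  y <- r * x + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
  cbind(x, y)
}

#' Plant ground-truth features for a paired-fluid experiment
#'
#' Draws per-feature, per-animal latent log2 abundances for both fluids. Every
#' variance component (feature baseline, animal deviation, dose response) is
#' drawn as a bivariate normal pair across fluids with correlation
#' `cross_fluid_r`, so the expected pooled serum-BALF log-intensity
#' correlation equals `cross_fluid_r` by construction. A fraction of features
#' is assigned a real peptide subsequence from the substrate database and its
#' theoretical MH+ as the feature mass; the rest are unidentifiable.
#'
#' @param db Substrate database `data.frame` from [read_substrate_fasta()].
#' @param design Study design from [generate_design()].
#' @param n_features Number of planted features.
#' @param class_props Named proportions over
#'   `c(null, modulated, exclusive, lost)`; must sum to 1.
#' @param effect_size Planted log2 fold change at the top dose for modulated
#'   features (default 1.0); intermediate doses scale linearly with dose.
#' @param cross_fluid_r Target serum-BALF correlation in `[-1, 1]`.
#' @param presence_props Named proportions over
#'   `c(serum_only, balf_only, both)`; the defaults reproduce the observed
#'   BALF/serum detection-depth ratio of ~0.29 and a ~45% BALF overlap.
#' @param identifiable_frac Fraction of features mapped to database
#'   subsequences (length 6-60, mass within the 1000-7000 Da peptidome
#'   window).
#' @param base_mean,base_sd Mean and sd of feature baseline log2 intensity.
#' @param animal_sd Sd of per-animal log2 deviation.
#' @param fluid_factor Multiplicative BALF concentration factor (default 0.3,
#'   emulating the 3-4 fold serum/BALF peptide concentration difference).
#' @param seed RNG seed.
#' @return Object of class `peptidome_truth`: list with `features`
#'   (`data.frame`), `latent_serum` / `latent_balf` (features x animals log2
#'   matrices, NA = truly absent) and `design`.
#' @export
generate_feature_truth <- function(db, design, n_features = 2000,
                                   class_props = c(null = 0.40, modulated = 0.30,
                                                   exclusive = 0.20, lost = 0.10),
                                   effect_size = 1.0, cross_fluid_r = 0.5,
                                   presence_props = c(serum_only = 0.75,
                                                      balf_only = 0.14,
                                                      both = 0.11),
                                   identifiable_frac = 0.05,
                                   base_mean = 14, base_sd = 1.5,
                                   animal_sd = 0.5, fluid_factor = 0.3,
                                   seed = 1) {
  if (nrow(db) == 0L) stop("empty substrate database", call. = FALSE)
  if (abs(sum(class_props) - 1) > 1e-8 || any(class_props < 0))
    stop("class_props must be nonnegative and sum to 1", call. = FALSE)
  if (abs(cross_fluid_r) > 1) stop("cross_fluid_r must lie in [-1, 1]", call. = FALSE)
  if (abs(sum(presence_props) - 1) > 1e-8)
    stop("presence_props must sum to 1", call. = FALSE)
  with_seed(seed, {
    animals <- unique(design[, c("animal", "dose")])
    n_anim <- nrow(animals)
    top_dose <- max(animals$dose)

    cls <- sample(names(class_props), n_features, replace = TRUE, prob = class_props)
    presence <- sample(names(presence_props), n_features, replace = TRUE,
                       prob = presence_props)

    n_ident <- round(identifiable_frac * n_features)
    sequence <- rep(NA_character_, n_features)
    mass <- stats::runif(n_features, 1000, 7000)
    if (n_ident > 0L) {
      idx <- sample.int(n_features, n_ident)
      for (i in idx) {
        for (try in 1:50) {
          prot <- db$sequence[sample.int(nrow(db), 1L)]
          len <- sample(6:min(60, nchar(prot)), 1L)
          start <- sample.int(nchar(prot) - len + 1L, 1L)
          pep <- substr(prot, start, start + len - 1L)
          mh <- peptide_mh(pep)
          if (mh >= 1000 && mh <= 7000) { sequence[i] <- pep; mass[i] <- mh; break }
        }
      }
    }
    rt <- stats::runif(n_features, 3, 62)
    drift <- sample(20:180, n_features, replace = TRUE)

    base <- .bivariate(n_features, cross_fluid_r) * base_sd + base_mean
    eff_raw <- .bivariate(n_features, cross_fluid_r)
    sign_s <- sample(c(-1, 1), n_features, replace = TRUE)
    # serum response magnitude is exactly effect_size; the BALF response is
    # the correlated counterpart with the same marginal scale
    eff_s <- sign_s * effect_size
    eff_b <- (cross_fluid_r * sign_s +
                sqrt(max(0, 1 - cross_fluid_r^2)) * eff_raw[, 2L]) * effect_size
    eff_s[cls != "modulated"] <- 0
    eff_b[cls != "modulated"] <- 0

    latent_s <- matrix(NA_real_, n_features, n_anim,
                       dimnames = list(NULL, animals$animal))
    latent_b <- latent_s
    for (a in seq_len(n_anim)) {
      dev <- .bivariate(n_features, cross_fluid_r) * animal_sd
      w <- DOSE_WEIGHT(animals$dose[a], top_dose)
      latent_s[, a] <- base[, 1L] + eff_s * w + dev[, 1L]
      latent_b[, a] <- base[, 2L] + log2(fluid_factor) + eff_b * w + dev[, 2L]
    }
    # class-driven absence: exclusive features never occur in vehicle
    # animals, lost features never occur in dosed animals
    vehicle <- animals$dose == 0
    latent_s[cls == "exclusive", vehicle] <- NA_real_
    latent_b[cls == "exclusive", vehicle] <- NA_real_
    latent_s[cls == "lost", !vehicle] <- NA_real_
    latent_b[cls == "lost", !vehicle] <- NA_real_
    # fluid presence
    latent_b[presence == "serum_only", ] <- NA_real_
    latent_s[presence == "balf_only", ] <- NA_real_

    features <- data.frame(
      feature_id = sprintf("F%04d", seq_len(n_features)),
      class = cls, presence = presence, sequence = sequence,
      rt = rt, drift = drift, mass = mass,
      effect_serum = eff_s, effect_balf = eff_b,
      stringsAsFactors = FALSE)
    rownames(latent_s) <- rownames(latent_b) <- features$feature_id
    structure(list(features = features, latent_serum = latent_s,
                   latent_balf = latent_b, design = design),
              class = "peptidome_truth")
  })
}

#' Emit per-sample ion-event tables from planted truth
#'
#' Every truly present feature emits at most one event per sample, jittered in
#' retention time, drift bin and mass; events below the limit of detection are
#' censored (dropped). Unclusterable noise events are added uniformly over the
#' RT x drift x mass acquisition box. Default jitter sigmas are one third of
#' the corresponding clustering tolerance, making true co-cluster membership a
#' ~3 sigma event.
#'
#' @param truth `peptidome_truth` from [generate_feature_truth()].
#' @param noise List with `sigma_rt` (min), `sigma_drift` (bins), `sigma_ppm`
#'   and `meas_cv` (multiplicative intensity CV).
#' @param lod Limit of detection on the intensity scale; events below it are
#'   dropped.
#' @param noise_rate Noise events as a fraction of true emitted events.
#' @param seed RNG seed.
#' @return `data.table` with columns `sample`, `rt_min`, `drift_bin`,
#'   `mass_da`, `intensity`, `true_feature` (NA for noise events).
#' @export
emit_ion_events <- function(truth,
                            noise = list(sigma_rt = 0.4, sigma_drift = 1,
                                         sigma_ppm = 3, meas_cv = 0.3),
                            lod = 512, noise_rate = 0.2, seed = 1) {
  if (!inherits(truth, "peptidome_truth")) stop("truth must be a peptidome_truth")
  if (!is.finite(lod) && lod > 0) { }  # +Inf allowed: total censoring
  if (lod <= 0) stop("lod must be positive", call. = FALSE)
  design <- truth$design
  sdlog <- sqrt(log(1 + noise$meas_cv^2))
  with_seed(seed, {
    out <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      lat <- if (design$fluid[i] == "serum") truth$latent_serum else truth$latent_balf
      vals <- lat[, design$animal[i]]
      present <- which(!is.na(vals))
      if (!length(present)) { out[[i]] <- NULL; next }
      f <- truth$features[present, ]
      intensity <- 2^vals[present] * exp(stats::rnorm(length(present), 0, sdlog))
      rt <- f$rt + stats::rnorm(length(present), 0, noise$sigma_rt)
      drift <- f$drift + round(stats::rnorm(length(present), 0, noise$sigma_drift))
      mass <- f$mass * (1 + stats::rnorm(length(present), 0, noise$sigma_ppm) / 1e6)
      keep <- intensity >= lod
      out[[i]] <- data.table::data.table(
        sample = design$sample[i],
        rt_min = pmin(pmax(rt[keep], 0), 65),
        drift_bin = pmin(pmax(drift[keep], 0L), 200L),
        mass_da = mass[keep],
        intensity = intensity[keep],
        true_feature = f$feature_id[keep])
    }
    events <- data.table::rbindlist(out)
    n_noise <- round(noise_rate * nrow(events))
    if (n_noise > 0L) {
      noise_int <- lod * 2^stats::runif(n_noise, 0.1, 4)
      noise_dt <- data.table::data.table(
        sample = sample(design$sample, n_noise, replace = TRUE),
        rt_min = stats::runif(n_noise, 0, 65),
        drift_bin = sample(0:200, n_noise, replace = TRUE),
        mass_da = stats::runif(n_noise, 1000, 7000),
        intensity = noise_int,
        true_feature = NA_character_)
      events <- data.table::rbindlist(list(events, noise_dt))
    }
    data.table::setorder(events, sample, mass_da)
    events[]
  })
}

#' Synthesize noisy fragment spectra for database peptides
#'
#' Builds the theoretical singly protonated b/y ladder of each peptide,
#' retains a random fraction of the fragments, jitters precursor and product
#' masses within the stated ppm bounds, and adds uniform noise peaks.
#'
#' @param sequences Character vector of peptide sequences.
#' @param frag_sampling Fraction of theoretical fragments retained, in (0, 1].
#' @param precursor_ppm_jitter,product_ppm_jitter Uniform jitter half-widths
#'   (ppm); defaults 2 and 4 keep spectra inside the 6/12 ppm search limits.
#' @param noise_peaks Number of uniform noise peaks per spectrum.
#' @param mods Residue mass table.
#' @param seed RNG seed.
#' @return List of spectra in the [read_mgf()] layout, with a `sequence`
#'   element recording the generating peptide.
#' @export
synthesize_spectra <- function(sequences, frag_sampling = 0.8,
                               precursor_ppm_jitter = 2,
                               product_ppm_jitter = 4,
                               noise_peaks = 5, mods = residue_table(),
                               seed = 1) {
  stopifnot(frag_sampling > 0, frag_sampling <= 1)
  with_seed(seed, {
    lapply(seq_along(sequences), function(i) {
      seq <- sequences[i]
      lad <- fragment_ladder(seq, mods)
      theo <- c(lad$b, lad$y)
      n_keep <- max(2L, round(frag_sampling * length(theo)))
      keep <- sort(sample.int(length(theo), n_keep))
      mz <- theo[keep] * (1 + stats::runif(n_keep, -product_ppm_jitter,
                                           product_ppm_jitter) / 1e6)
      intensity <- stats::runif(n_keep, 20, 100)
      if (noise_peaks > 0L) {
        mz <- c(mz, stats::runif(noise_peaks, min(theo) * 0.5, lad$mh))
        intensity <- c(intensity, stats::runif(noise_peaks, 1, 15))
      }
      ord <- order(mz)
      peaks <- cbind(mz = mz[ord], intensity = intensity[ord])
      list(title = sprintf("synthetic_%04d", i),
           precursor_mh = lad$mh * (1 + stats::runif(1, -precursor_ppm_jitter,
                                                     precursor_ppm_jitter) / 1e6),
           rt = NA_real_, peaks = peaks, sequence = seq)
    })
  })
}

#' Build the bundled synthetic substrate database
#'
#' Constructs a ~50-protein toy search space from the bundled table of
#' identified peptide sequences: peptides sharing a parent protein are
#' concatenated and padded with random flanking residues into one synthetic
#' record per protein, preserving the MEROPS/SignalP source tags. The records
#' are synthetic stand-ins, not real protein sequences; only the embedded
#' peptides are authentic.
#'
#' @param seed RNG seed for the flanking residues.
#' @param flank Number of random residues added on each side of the embedded
#'   block.
#' @return Substrate database `data.frame` (see [read_substrate_fasta()]).
#' @export
build_toy_substrate_db <- function(seed = 42, flank = 25) {
  tab <- read_tsv_dt(peptidome_example("table1_peptides.tsv"))
  with_seed(seed, {
    alphabet <- names(RESIDUE_MASSES)
    by_prot <- split(tab, tab$symbol)
    recs <- lapply(by_prot, function(g) {
      block <- paste(unique(g$sequence), collapse = "")
      left <- paste(sample(alphabet, flank, replace = TRUE), collapse = "")
      right <- paste(sample(alphabet, flank, replace = TRUE), collapse = "")
      src <- sort(unique(unlist(strsplit(g$source, ",", fixed = TRUE))))
      # accessions in the source table may carry homologue suffixes or
      # separators; keep the first clean token, or fall back to a synthetic id
      acc <- sub("[^A-Za-z0-9].*$", "", g$accession[1L])
      if (nchar(acc) < 6L) acc <- paste0("SYN", g$symbol[1L])
      data.frame(accession = acc, symbol = g$symbol[1L],
                 source = paste(src, collapse = ","),
                 description = paste0(g$protein_name[1L], " (synthetic excerpt)"),
                 sequence = paste0(left, block, right),
                 stringsAsFactors = FALSE)
    })
    db <- do.call(rbind, recs)
    rownames(db) <- NULL
    db[order(db$symbol), ]
  })
}
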