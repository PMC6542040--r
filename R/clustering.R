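# Tolerance-box clustering of ion events across samples into features, and
# the replicate reproducibility filter.
#
# The clustering is greedy and seeded: events are sorted by descending
# intensity; the most intense unassigned event seeds a feature and captures
# all unassigned events inside the tolerance box around the seed, keeping at
# most one event per sample (nearest by tolerance-normalized Euclidean
# distance). Tolerances are measured from the seed, not a running centroid,
# which prevents drift-dependent chaining; the centroid is recomputed once at
# the end for reporting. A mass-sorted index makes each capture a window
# query, so the sweep is linearithmic rather than all-pairs.

#' Clustering tolerance box
#'
#' @param rt Retention-time tolerance in minutes (default +/-2).
#' @param drift Drift-time tolerance in bins (default +/-4).
#' @param ppm Mass tolerance in ppm (default +/-12).
#' @return List of class `tolerance_box`.
#' @export
tolerance_box <- function(rt = 2.0, drift = 4, ppm = 12) {
  if (rt <= 0 || drift <= 0 || ppm <= 0)
    stop("all tolerances must be strictly positive", call. = FALSE)
  structure(list(rt = rt, drift = drift, ppm = ppm), class = "tolerance_box")
}

#' Cluster ion events across samples into features
#'
#' Partitions all events (both fluids, all samples, clustered jointly) into
#' features by greedy seeded capture within a retention-time / drift / mass
#' tolerance box. Deterministic: intensity ties are broken by
#' (mass, rt, drift, sample) lexicographic order.
#'
#' @param events `data.table`/`data.frame` with columns `sample`, `rt_min`,
#'   `drift_bin`, `mass_da`, `intensity`.
#' @param box [tolerance_box()].
#' @return `data.table` of the input events with added columns `feature_id`
#'   and attribute `"centroids"`: a `data.table` of per-feature centroids
#'   (`feature_id`, `rt`, `drift`, `mass`, `n_events`).
#' @export
cluster_events <- function(events, box = tolerance_box()) {
  stopifnot(inherits(box, "tolerance_box"))
  events <- data.table::as.data.table(events)
  n <- nrow(events)
  if (n == 0L) {
    res <- data.table::copy(events)
    res[, feature_id := character(0)]
    data.table::setattr(res, "centroids",
                        data.table::data.table(feature_id = character(0),
                                               rt = numeric(0), drift = numeric(0),
                                               mass = numeric(0), n_events = integer(0)))
    return(res[])
  }
  required <- c("sample", "rt_min", "drift_bin", "mass_da", "intensity")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols))
    stop("events table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  ord_mass <- order(events$mass_da)
  mass_sorted <- events$mass_da[ord_mass]
  # seed order: descending intensity, deterministic tie-break
  seed_order <- order(-events$intensity, events$mass_da, events$rt_min,
                      events$drift_bin, events$sample)

  assigned <- integer(n)  # 0 = unassigned, else feature index
  feat <- 0L
  rtv <- events$rt_min; drv <- events$drift_bin; msv <- events$mass_da
  smp <- events$sample
  for (s in seed_order) {
    if (assigned[s] != 0L) next
    feat <- feat + 1L
    m0 <- msv[s]
    dm <- box$ppm * m0 / 1e6
    lo <- findInterval(m0 - dm, mass_sorted) + 1L
    hi <- findInterval(m0 + dm + 1e-12, mass_sorted)
    cand <- ord_mass[lo:hi]
    cand <- cand[assigned[cand] == 0L &
                   abs(rtv[cand] - rtv[s]) <= box$rt &
                   abs(drv[cand] - drv[s]) <= box$drift]
    if (length(cand) > 1L) {
      # at most one member per sample: nearest in tolerance-normalized space
      d2 <- ((rtv[cand] - rtv[s]) / box$rt)^2 +
        ((drv[cand] - drv[s]) / box$drift)^2 +
        ((msv[cand] - m0) / dm)^2
      keep_ord <- cand[order(d2, msv[cand], rtv[cand])]
      cand <- keep_ord[!duplicated(smp[keep_ord])]
    }
    assigned[cand] <- feat
  }

  res <- data.table::copy(events)
  res[, feature_id := sprintf("C%05d", assigned)]
  centroids <- res[, .(rt = mean(rt_min), drift = mean(drift_bin),
                       mass = mean(mass_da), n_events = .N),
                   by = feature_id][order(feature_id)]
  data.table::setattr(res, "centroids", centroids)
  res[]
}

#' Group-wise detection counts for clustered features
#'
#' @param clustered Output of [cluster_events()].
#' @param design Study design.
#' @return `data.table` with one row per feature x (fluid, dose) group:
#'   `feature_id`, `fluid`, `dose`, `n_detected`, `group_size`.
#' @keywords internal
detection_counts <- function(clustered, design) {
  unknown <- setdiff(unique(clustered$sample), design$sample)
  if (length(unknown))
    stop("sample(s) absent from design: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  dd <- data.table::as.data.table(design)
  groups <- dd[, .(group_size = .N), by = .(fluid, dose)]
  det <- merge(clustered[, .(feature_id, sample)], dd, by = "sample")
  counts <- det[, .(n_detected = data.table::uniqueN(sample)),
                by = .(feature_id, fluid, dose)]
  grid <- data.table::CJ(feature_id = unique(clustered$feature_id),
                         fluid = groups$fluid, dose = groups$dose, unique = TRUE)
  grid <- merge(grid, groups, by = c("fluid", "dose"))
  out <- merge(grid, counts, by = c("feature_id", "fluid", "dose"), all.x = TRUE)
  out[is.na(n_detected), n_detected := 0L]
  out[]
}

#' Replicate reproducibility filter
#'
#' Keeps a feature iff, within at least one (fluid x dose) group, it was
#' detected in at least `ceiling(min_frac * group_size)` biological
#' replicates (two-thirds of n = 6 is 4).
#'
#' @param clustered Output of [cluster_events()].
#' @param design Study design.
#' @param min_frac Minimum detection fraction within a group (default 2/3).
#' @return Filtered event table (same shape as input) with attribute
#'   `"detections"` carrying the group-wise detection counts of the retained
#'   features.
#' @export
reproducibility_filter <- function(clustered, design, min_frac = 2 / 3) {
  counts <- detection_counts(clustered, design)
  counts[, required := ceiling(min_frac * group_size)]
  keep <- unique(counts[n_detected >= required, feature_id])
  res <- clustered[feature_id %in% keep]
  data.table::setattr(res, "detections", counts[feature_id %in% keep])
  data.table::setattr(res, "centroids",
                      attr(clustered, "centroids")[feature_id %in% keep])
  res[]
}

#' Serum/BALF overlap report
#'
#' A feature is "common" iff it passes the reproducibility criterion in at
#' least one group of each fluid; otherwise it is serum-only or BALF-only.
#'
#' @param clustered Clustered (unfiltered or filtered) event table.
#' @param design Study design covering both fluids.
#' @param min_frac Reproducibility fraction (default 2/3).
#' @return List with counts `serum_only`, `balf_only`, `common`, `total`.
#' @export
overlap_report <- function(clustered, design, min_frac = 2 / 3) {
  if (length(unique(design$fluid)) < 2L)
    stop("overlap report requires both fluids in the design", call. = FALSE)
  counts <- detection_counts(clustered, design)
  counts[, ok := n_detected >= ceiling(min_frac * group_size)]
  per_fluid <- counts[, .(reproducible = any(ok)), by = .(feature_id, fluid)]
  wide <- data.table::dcast(per_fluid, feature_id ~ fluid,
                            value.var = "reproducible", fill = FALSE)
  if (!"serum" %in% names(wide)) wide[, serum := FALSE]
  if (!"BALF" %in% names(wide)) wide[, BALF := FALSE]
  list(serum_only = sum(wide$serum & !wide$BALF),
       balf_only = sum(wide$BALF & !wide$serum),
       common = sum(wide$serum & wide$BALF),
       total = nrow(wide))
}

#' Build the feature intensity matrix from clustered events
#'
#' @param clustered Clustered (typically reproducibility-filtered) events.
#' @param design Study design (defines column order).
#' @return Numeric matrix features x samples, NA = not detected, with
#'   attribute `transform = "raw"`.
#' @export
feature_matrix <- function(clustered, design) {
  wide <- data.table::dcast(clustered, feature_id ~ sample,
                            value.var = "intensity",
                            fun.aggregate = max, fill = NA_real_)
  m <- as.matrix(wide[, -1L])
  rownames(m) <- wide$feature_id
  missing_samples <- setdiff(design$sample, colnames(m))
  if (length(missing_samples)) {
    m <- cbind(m, matrix(NA_real_, nrow(m), length(missing_samples),
                         dimnames = list(NULL, missing_samples)))
  }
  m <- m[, design$sample, drop = FALSE]
  attr(m, "transform") <- "raw"
  m
}
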