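# Quantitation on the clustered feature matrix: group-wise LOQ estimation,
# imputation of group-wise absent features, median centering / log2
# transformation, fold changes against vehicle, and single-point
# concentration approximation.

.check_raw <- function(m) {
  if (!identical(attr(m, "transform"), "raw"))
    stop("expected a raw (untransformed) feature matrix", call. = FALSE)
}

.group_samples <- function(design) {
  split(design$sample, interaction(design$fluid, design$dose, drop = TRUE))
}

#' Estimate the per-group limit of quantification
#'
#' The LOQ of a (fluid x dose) group is a low quantile (default 5%) of all
#' observed intensities in the group; its CV is the pooled coefficient of
#' variation of the features whose group mean lies in the lowest decile of
#' group means — i.e. the variability of quantification near the detection
#' floor.
#'
#' @param m Raw feature matrix from [feature_matrix()].
#' @param design Study design.
#' @param quantile Lower quantile defining the LOQ (default 0.05).
#' @param fallback_cv CV used when too few low features are observed to pool
#'   a CV (default 0.3).
#' @return `data.frame` with columns `fluid`, `dose`, `loq`, `cv`.
#' @export
estimate_group_loq <- function(m, design, quantile = 0.05, fallback_cv = 0.3) {
  .check_raw(m)
  groups <- unique(design[, c("fluid", "dose")])
  res <- lapply(seq_len(nrow(groups)), function(i) {
    cols <- design$sample[design$fluid == groups$fluid[i] &
                            design$dose == groups$dose[i]]
    sub <- m[, cols, drop = FALSE]
    obs <- sub[!is.na(sub)]
    if (!length(obs))
      stop(sprintf("group %s/%g has no observed intensities",
                   groups$fluid[i], groups$dose[i]), call. = FALSE)
    loq <- stats::quantile(obs, quantile, names = FALSE)
    gm <- rowMeans(sub, na.rm = TRUE)
    low <- which(gm <= stats::quantile(gm[is.finite(gm)], 0.1, names = FALSE))
    cvs <- apply(sub[low, , drop = FALSE], 1L, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2L || mean(x) == 0) NA_real_ else stats::sd(x) / mean(x)
    })
    cv <- if (all(is.na(cvs))) fallback_cv else mean(cvs, na.rm = TRUE)
    if (!is.finite(cv) || cv <= 0) cv <- fallback_cv
    data.frame(fluid = groups$fluid[i], dose = groups$dose[i],
               loq = loq, cv = cv, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Impute group-wise absent features at the group LOQ
#'
#' Only feature x group cells in which the feature was detected in zero
#' replicates of that group are filled ("categorically below the limit of
#' detection"); the fills are draws from a zero-truncated normal with mean =
#' group LOQ and sd = CV x LOQ. Cells in groups with at least one detection
#' are left missing and handled pairwise by downstream statistics.
#'
#' @param m Raw feature matrix.
#' @param design Study design.
#' @param loq Output of [estimate_group_loq()].
#' @param seed RNG seed (imputation is deterministic per seed).
#' @return Matrix of the same shape with imputed cells filled; attribute
#'   `imputed` holds a logical matrix marking them.
#' @export
impute_below_lod <- function(m, design, loq, seed = 1) {
  .check_raw(m)
  imputed <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  out <- m
  with_seed(seed, {
    for (i in seq_len(nrow(loq))) {
      cols <- design$sample[design$fluid == loq$fluid[i] &
                              design$dose == loq$dose[i]]
      sub <- out[, cols, drop = FALSE]
      all_missing <- rowSums(!is.na(sub)) == 0L
      if (!any(all_missing)) next
      n_fill <- sum(all_missing) * length(cols)
      mu <- loq$loq[i]; sdv <- loq$cv[i] * mu
      draws <- stats::rnorm(n_fill, mu, sdv)
      # zero-truncation by redraw; at CV <= 0.5 rejections are rare
      while (any(draws <= 0))
        draws[draws <= 0] <- stats::rnorm(sum(draws <= 0), mu, sdv)
      out[all_missing, cols] <- matrix(draws, ncol = length(cols))
      imputed[all_missing, cols] <- TRUE
    }
  })
  attr(out, "transform") <- "raw"
  attr(out, "imputed") <- imputed
  out
}

#' Median centering and log2 transformation
#'
#' Per sample: log2-transform observed intensities, subtract the sample
#' median, then add the grand median (median of per-sample medians) so values
#' stay on a common log2-intensity scale. Records the transform state; the
#' transformation refuses to run twice.
#'
#' @param m Raw feature matrix (strictly positive observed values).
#' @return Matrix with attribute `transform = "normalized-log2"`.
#' @export
normalize_log2 <- function(m) {
  .check_raw(m)
  if (any(m[!is.na(m)] <= 0))
    stop("nonpositive intensities cannot be log2 transformed", call. = FALSE)
  lg <- log2(m)
  # centering medians are computed over genuinely observed cells: imputed
  # LOQ placeholders are group-absence markers, not sample loading, and
  # would otherwise shift medians of the groups that carry them
  obs <- lg
  imp <- attr(m, "imputed")
  if (!is.null(imp)) obs[imp] <- NA_real_
  med <- apply(obs, 2L, stats::median, na.rm = TRUE)
  grand <- stats::median(med)
  out <- sweep(lg, 2L, med - grand)
  attrs <- attributes(m)
  attr(out, "imputed") <- attrs$imputed
  attr(out, "transform") <- "normalized-log2"
  out
}

#' Per-feature log2 fold change relative to vehicle
#'
#' FC(feature, dose) = mean(log2 intensity, dosed group) - mean(log2
#' intensity, vehicle group), computed per fluid over observed (and imputed)
#' values.
#'
#' @param m Normalized matrix from [normalize_log2()].
#' @param design Study design; a dose-0 group must be present in each fluid.
#' @return `data.table` with columns `feature_id`, `fluid`, `dose`,
#'   `log2_fc`.
#' @export
fold_change <- function(m, design) {
  if (!identical(attr(m, "transform"), "normalized-log2"))
    stop("fold_change expects a normalized-log2 matrix", call. = FALSE)
  fluids <- unique(design$fluid)
  out <- list()
  for (fl in fluids) {
    dsub <- design[design$fluid == fl, ]
    if (!any(dsub$dose == 0))
      stop("no dose-0 (vehicle) group for fluid ", fl, call. = FALSE)
    ref_cols <- dsub$sample[dsub$dose == 0]
    ref <- rowMeans(m[, ref_cols, drop = FALSE], na.rm = TRUE)
    for (d in setdiff(unique(dsub$dose), 0)) {
      cols <- dsub$sample[dsub$dose == d]
      fc <- rowMeans(m[, cols, drop = FALSE], na.rm = TRUE) - ref
      out[[length(out) + 1L]] <- data.table::data.table(
        feature_id = rownames(m), fluid = fl, dose = d, log2_fc = fc)
    }
  }
  data.table::rbindlist(out)
}

#' Single-point concentration approximation
#'
#' Approximates a peptide concentration from its mean intensity and the mean
#' instrument response to a known peptide concentration (intensity units per
#' nM).
#'
#' @param mean_intensity Mean feature intensity (raw scale).
#' @param response_factor Instrument response, intensity per nM (> 0).
#' @return Estimated concentration in nM.
#' @export
estimate_concentration <- function(mean_intensity, response_factor) {
  if (any(response_factor <= 0))
    stop("response_factor must be positive", call. = FALSE)
  mean_intensity / response_factor
}
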