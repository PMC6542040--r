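# Differential statistics: per-feature one-way dose ANOVA, Benjamini-Hochberg
# FDR control, exclusivity classification from detection calls, and the
# paired cross-fluid regression.

#' Per-feature one-way ANOVA across dose groups
#'
#' Classical fixed-effects one-way ANOVA of log2 intensity on dose group,
#' computed per feature within one fluid. Features with fewer than two groups
#' having two or more observations are marked untestable (`NA` F, p = 1);
#' all-constant features get p = 1 by convention.
#'
#' @param m Normalized-log2 feature matrix.
#' @param design Study design.
#' @param fluid Which fluid to test (`"serum"` or `"BALF"`).
#' @return `data.table` with `feature_id`, `f_stat`, `p_value`, `testable`.
#' @export
anova_per_feature <- function(m, design, fluid = "serum") {
  dsub <- design[design$fluid == fluid, ]
  if (!nrow(dsub)) stop("no samples for fluid ", fluid, call. = FALSE)
  cols <- dsub$sample
  grp <- factor(dsub$dose)
  sub <- m[, cols, drop = FALSE]
  res <- apply(sub, 1L, function(x) {
    obs <- !is.na(x)
    g <- grp[obs]; x <- x[obs]
    counts <- table(g)
    usable <- counts >= 2L
    if (sum(usable) < 2L) return(c(NA_real_, 1, 0))
    keep <- g %in% names(counts)[usable]
    x <- x[keep]; g <- droplevels(g[keep])
    k <- nlevels(g); n <- length(x)
    gm <- tapply(x, g, mean); gn <- tapply(x, g, length)
    ssb <- sum(gn * (gm - mean(x))^2)
    ssw <- sum((x - gm[g])^2)
    if (ssw <= .Machine$double.eps * max(1, abs(ssb))) {
      if (ssb <= .Machine$double.eps) return(c(NA_real_, 1, 1))  # all constant
      return(c(Inf, 0, 1))
    }
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    c(f, stats::pf(f, k - 1, n - k, lower.tail = FALSE), 1)
  })
  data.table::data.table(feature_id = rownames(m),
                         f_stat = res[1L, ], p_value = res[2L, ],
                         testable = res[3L, ] == 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p P values in `[0, 1]` (untestable features enter as p = 1 and stay
#'   in the denominator m).
#' @param alpha FDR level for the significance flags (default 0.05).
#' @return `data.frame` with `p`, `q` (monotone BH-adjusted values) and
#'   `significant` (`q <= alpha`).
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[ord] <- cummin(p[ord] * m / rank(p, ties.method = "max")[ord])
  q <- pmin(q, 1)
  data.frame(p = p, q = q, significant = q <= alpha)
}

#' Classify feature exclusivity from detection calls
#'
#' Exposure-exclusive: reproducibly detected in at least one dosed group and
#' in zero vehicle replicates. Lost: reproducibly detected in vehicle and in
#' zero replicates of every dosed group. Otherwise "modulated" if the
#' ANOVA/BH flag is set, else "null". Calls are per fluid; a feature is
#' classified on its union across fluids where present.
#'
#' @param detections Detection counts (attribute `"detections"` of
#'   [reproducibility_filter()] output).
#' @param significant Named logical vector of BH flags keyed by feature id
#'   (optional; default none).
#' @param min_frac Reproducibility fraction (default 2/3).
#' @return `data.table` with `feature_id`, `class`.
#' @export
classify_exclusivity <- function(detections, significant = NULL, min_frac = 2 / 3) {
  det <- data.table::as.data.table(detections)
  det[, reproducible := n_detected >= ceiling(min_frac * group_size)]
  cls <- det[, {
    veh <- dose == 0
    veh_det <- sum(n_detected[veh])
    dosed_det <- sum(n_detected[!veh])
    excl <- any(reproducible[!veh]) && veh_det == 0L
    lost <- any(reproducible[veh]) && dosed_det == 0L
    .(class = if (excl) "exclusive" else if (lost) "lost" else "tested")
  }, by = feature_id]
  if (!is.null(significant)) {
    flag <- significant[cls$feature_id]
    flag[is.na(flag)] <- FALSE
  } else {
    flag <- rep(FALSE, nrow(cls))
  }
  tested <- cls$class == "tested"
  cls$class[tested] <- ifelse(flag[tested], "modulated", "null")
  cls[]
}

#' Paired serum-BALF regression within a dose group
#'
#' Ordinary least squares of serum log2 intensity on BALF log2 intensity,
#' pooling one point per (significant feature, animal) pair within the dose
#' group. Reports the correlation coefficient R (carrying the slope's sign),
#' the regression F statistic and p value.
#'
#' @param m Normalized-log2 matrix covering both fluids.
#' @param design Study design (paired by `animal`).
#' @param features Feature ids to include (typically BH-significant ones).
#' @param dose Dose group to fit.
#' @return List of class `crossfluid_fit` with `dose`, `slope`, `intercept`,
#'   `r`, `f_stat`, `p_value`, `n_points`, `n_features`.
#' @export
crossfluid_regression <- function(m, design, features, dose) {
  dsub <- design[design$dose == dose, ]
  serum <- dsub[dsub$fluid == "serum", ]
  balf <- dsub[dsub$fluid == "BALF", ]
  balf <- balf[match(serum$animal, balf$animal), ]
  if (!nrow(serum) || any(is.na(balf$sample)))
    stop("design is not serum-BALF paired for dose ", dose, call. = FALSE)
  features <- intersect(features, rownames(m))
  # imputed cells are LOQ noise, not measurements: the regression is fit on
  # genuinely observed pairs only (pairwise-complete)
  imp <- attr(m, "imputed")
  mm <- m
  if (!is.null(imp)) mm[imp] <- NA_real_
  x <- as.vector(mm[features, balf$sample, drop = FALSE])
  y <- as.vector(mm[features, serum$sample, drop = FALSE])
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("fewer than 3 complete pairs for dose ", dose, call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate variance in paired intensities", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  structure(list(dose = dose,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r = sign(slope) * sqrt(sm$r.squared),
                 f_stat = unname(sm$fstatistic[1L]),
                 p_value = stats::pf(sm$fstatistic[1L], sm$fstatistic[2L],
                                     sm$fstatistic[3L], lower.tail = FALSE),
                 n_points = length(x),
                 n_features = length(features)),
            class = "crossfluid_fit")
}

#' Differential table for one fluid
#'
#' Convenience wrapper combining ANOVA, BH adjustment, fold changes and
#' exclusivity classes into one volcano-ready table.
#'
#' @param m Normalized-log2 matrix.
#' @param design Study design.
#' @param detections Detection counts from [reproducibility_filter()].
#' @param fluid Fluid to test.
#' @param alpha FDR level.
#' @return `data.table`: `feature_id`, `f_stat`, `p_value`, `q_value`,
#'   `significant`, `class`, one `log2_fc_<dose>` column per dosed group and
#'   `neg_log10_p`.
#' @export
differential_table <- function(m, design, detections, fluid = "serum",
                               alpha = 0.05) {
  an <- anova_per_feature(m, design, fluid)
  adj <- bh_adjust(an$p_value, alpha)
  an[, `:=`(q_value = adj$q, significant = adj$significant)]
  flags <- stats::setNames(an$significant, an$feature_id)
  det <- data.table::as.data.table(detections)
  det_idx <- which(det[["fluid"]] == fluid)
  det <- det[det_idx]
  cls <- classify_exclusivity(det, flags)
  fc <- fold_change(m, design)
  fc_idx <- which(fc[["fluid"]] == fluid)
  fc <- fc[fc_idx]
  fcw <- data.table::dcast(fc, feature_id ~ paste0("log2_fc_", dose),
                           value.var = "log2_fc")
  out <- merge(an, cls, by = "feature_id", all.x = TRUE)
  out <- merge(out, fcw, by = "feature_id", all.x = TRUE)
  out[is.na(class), class := "null"]
  out[, neg_log10_p := -log10(pmax(p_value, .Machine$double.xmin))]
  out[]
}
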