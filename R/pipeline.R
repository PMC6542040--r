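# End-to-end orchestration: simulate -> cluster -> quantify -> stats ->
# identify, with a serializable run configuration and a JSON run report.

#' Default run configuration
#'
#' All stage parameters in one serializable list. A single master seed fans
#' out deterministically to per-stage seeds via [derive_seed()], so any stage
#' can be re-run in isolation reproducibly.
#'
#' @param seed Master seed.
#' @return Nested named list of class `peptidome_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    simulate = list(n_per_group = 6, doses = c(0, 10, 40), n_features = 2000,
                    class_props = c(null = 0.40, modulated = 0.30,
                                    exclusive = 0.20, lost = 0.10),
                    effect_size = 1.0, cross_fluid_r = 0.5,
                    presence_props = c(serum_only = 0.75, balf_only = 0.14,
                                       both = 0.11),
                    identifiable_frac = 0.05, fluid_factor = 0.3,
                    lod = 512, noise_rate = 0.2,
                    n_spectra = 40, frag_sampling = 0.8),
    cluster = list(rt_tol = 2.0, drift_tol = 4, ppm_tol = 12, min_frac = 2 / 3),
    quantify = list(loq_quantile = 0.05),
    stats = list(alpha = 0.05),
    identify = list(precursor_ppm = 6, product_ppm = 12, fdr = 0.10,
                    min_len = 6, max_len = 80, decoy_seed = 7),
    stages = c("simulate", "cluster", "quantify", "stats", "identify")
  ), class = "peptidome_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @param config Configuration list.
#' @name config-io
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_config())
  for (k in names(cfg)) {
    if (is.list(base[[k]]) && is.list(cfg[[k]])) {
      vals <- cfg[[k]]
      # named numeric vectors round-trip through YAML as named lists
      for (kk in names(vals)) base[[k]][[kk]] <- .restore_vec(base[[k]][[kk]], vals[[kk]])
    } else {
      base[[k]] <- .restore_vec(base[[k]], cfg[[k]])
    }
  }
  structure(base, class = "peptidome_config")
}

.restore_vec <- function(template, value) {
  if (is.list(value) && !is.null(names(value)) && !is.list(template))
    return(unlist(value))
  if (is.list(value) && is.null(names(value))) return(unlist(value))
  value
}

#' @rdname config-io
#' @export
write_config <- function(config, path) {
  # named atomic vectors must become YAML maps or their names are lost
  yamlify <- function(x) {
    if (is.list(x)) return(lapply(x, yamlify))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  yaml::write_yaml(yamlify(unclass(config)), path, precision = 15)
  invisible(path)
}

#' Run the full synthetic-data pipeline
#'
#' Executes the enabled stages in order on synthetic data and writes all
#' intermediate tables, the effective configuration and a JSON run report
#' into `out_dir`. Identical configuration implies byte-identical outputs.
#'
#' @param config Configuration from [default_config()] or [read_config()].
#' @param out_dir Output directory (created if missing).
#' @return The run report (list), invisibly also written to
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  report <- list(seed = config$seed, stages = as.list(stages))

  db <- build_toy_substrate_db(seed = derive_seed(config$seed, "db"))
  write_substrate_fasta(db, file.path(out_dir, "substrates_synthetic.fasta"))

  sim <- config$simulate
  design <- generate_design(sim$n_per_group, sim$doses,
                            derive_seed(config$seed, "design"))
  truth <- generate_feature_truth(
    db, design, n_features = sim$n_features, class_props = sim$class_props,
    effect_size = sim$effect_size, cross_fluid_r = sim$cross_fluid_r,
    presence_props = sim$presence_props,
    identifiable_frac = sim$identifiable_frac, fluid_factor = sim$fluid_factor,
    seed = derive_seed(config$seed, "truth"))
  events <- emit_ion_events(truth, lod = sim$lod, noise_rate = sim$noise_rate,
                            seed = derive_seed(config$seed, "events"))
  write_tsv_dt(design, file.path(out_dir, "design.tsv"))
  write_tsv_dt(events[, c("sample", "rt_min", "drift_bin", "mass_da",
                          "intensity")],
               file.path(out_dir, "ion_events.tsv"))
  ident_seqs <- truth$features$sequence[!is.na(truth$features$sequence)]
  spectra <- list()
  if (length(ident_seqs)) {
    picked <- utils::head(ident_seqs, sim$n_spectra)
    spectra <- synthesize_spectra(picked, frag_sampling = sim$frag_sampling,
                                  seed = derive_seed(config$seed, "spectra"))
    write_mgf(spectra, file.path(out_dir, "spectra.mgf"))
  }
  report$simulate <- list(n_samples = nrow(design), n_events = nrow(events),
                          n_features_planted = sim$n_features,
                          n_spectra = length(spectra))

  if ("cluster" %in% stages) {
    cl <- config$cluster
    box <- tolerance_box(cl$rt_tol, cl$drift_tol, cl$ppm_tol)
    clustered <- cluster_events(events, box)
    filtered <- reproducibility_filter(clustered, design, cl$min_frac)
    ov <- overlap_report(clustered, design, cl$min_frac)
    m <- feature_matrix(filtered, design)
    write_tsv_dt(data.table::data.table(feature_id = rownames(m), m),
                 file.path(out_dir, "feature_matrix.tsv"))
    write_tsv_dt(attr(filtered, "centroids"),
                 file.path(out_dir, "feature_centroids.tsv"))
    report$cluster <- list(
      n_features_total = length(unique(clustered$feature_id)),
      n_reproducible = length(unique(filtered$feature_id)),
      overlap = ov)
  }

  if ("quantify" %in% stages && "cluster" %in% stages) {
    loq <- estimate_group_loq(m, design, config$quantify$loq_quantile)
    imp <- impute_below_lod(m, design, loq,
                            seed = derive_seed(config$seed, "impute"))
    norm <- normalize_log2(imp)
    report$quantify <- list(n_imputed_cells = sum(attr(imp, "imputed")),
                            loq = loq)
  }

  if ("stats" %in% stages && "quantify" %in% stages && "cluster" %in% stages) {
    detections <- attr(filtered, "detections")
    diff_tabs <- list()
    for (fl in unique(design$fluid)) {
      dt <- differential_table(norm, design, detections, fl,
                               config$stats$alpha)
      write_tsv_dt(dt, file.path(out_dir, sprintf("differential_%s.tsv", fl)))
      diff_tabs[[fl]] <- dt
    }
    sig <- diff_tabs$serum$feature_id[diff_tabs$serum$significant]
    fits <- list()
    for (d in setdiff(unique(design$dose), 0)) {
      fit <- tryCatch(crossfluid_regression(norm, design, sig, d),
                      error = function(e) NULL)
      if (!is.null(fit))
        fits[[as.character(d)]] <- fit[c("dose", "slope", "intercept", "r",
                                         "f_stat", "p_value", "n_points")]
    }
    report$stats <- list(
      significant = lapply(diff_tabs, function(x) sum(x$significant)),
      classes = lapply(diff_tabs, function(x) as.list(table(x$class))),
      regression = fits)
  }

  if ("identify" %in% stages && length(spectra)) {
    idc <- config$identify
    index <- build_index(db)
    res <- decoy_search(spectra, index, idc$precursor_ppm, idc$product_ppm,
                        c(idc$min_len, idc$max_len), idc$decoy_seed)
    scored <- fdr_threshold(res$target, res$decoy, idc$fdr)
    accepted <- scored[scored$accepted]
    ann <- if (nrow(accepted))
      do.call(rbind, lapply(seq_len(nrow(accepted)), function(i)
        annotate_match(accepted[i], index)))
    else NULL
    if (!is.null(ann))
      write_tsv_dt(ann, file.path(out_dir, "identifications.tsv"))
    report$identify <- list(n_spectra = length(spectra),
                            n_target_matches = nrow(res$target),
                            n_accepted = nrow(accepted))
  }

  write_config(config, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}

#' Validate theoretical masses against the bundled identification table
#'
#' Recomputes the residue-sum mass (fixed carbamidomethyl-C) of every peptide
#' sequence in the bundled identification table and compares it with the
#' printed peptide mass, flagging any row off by more than `tol` Da.
#'
#' @param path Table TSV with columns `sequence` and `peptide_mass`; default
#'   the bundled table.
#' @param tol Allowed absolute deviation in Da (default 0.001).
#' @return `data.table` with `sequence`, `peptide_mass`, `computed_mass`,
#'   `delta_da`, `pass`.
#' @export
validate_against_table1 <- function(path = peptidome_example("table1_peptides.tsv"),
                                    tol = 0.001) {
  tab <- read_tsv_dt(path)
  if (!all(c("sequence", "peptide_mass") %in% names(tab)))
    stop("table must have 'sequence' and 'peptide_mass' columns", call. = FALSE)
  tab[, computed_mass := vapply(sequence, residue_mass_sum, 0)]
  tab[, delta_da := computed_mass - peptide_mass]
  tab[, pass := abs(delta_da) <= tol]
  tab[, .(sequence, peptide_mass, computed_mass, delta_da, pass)]
}
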