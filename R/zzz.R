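.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "feature_id", "rt_min", "drift_bin", "mass_da", "intensity",
  "required", "n_detected", "group_size", "ok", "fluid", "dose", "serum",
  "BALF", "sequence", "peptide_mass", "pass", "computed_mass", "delta_da",
  "true_feature", "q_value", "score", "decoy", "symbol", "reproducible",
  "class", "neg_log10_p", "significant", "accessions", "accepted", "start",
  "end", "protein", "theoretical_mh", "ppm", "q", "p_value", "f_stat",
  "testable", "log2_fc"
))
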