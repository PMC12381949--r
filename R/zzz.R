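#' @importFrom data.table := .N .SD data.table as.data.table setorder CJ
#' @importFrom stats setNames
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "..wt_vec", ".wt", "o", "e", "py", "rate", "cancer_type",
  "age_band_start", "year", "imd_fifth", "id", "time", "invasive",
  "laterality", "role", "included", "reason", "event_time", "entry", "exit",
  "i.entry", "i.exit", "age_dx", "year_dx", "start", "end", "len", "window",
  "d_target", "d_comp", "cens", "ratelen", "R_obs", "R_exp", "excess",
  "S", "S_exp", "e_hat", "p_target", "n_eff", "band_lo", "band_hi",
  "row", "t", "fu_start", "events", "age_band", "year_grp", "radiotherapy",
  "endocrine", "chemotherapy", "mastectomy", "stratum", "flagged", "rr",
  "count", "af", "trial_consistent", "exposure", "period", "adjusted",
  "level", "converged", "lo", "hi", "p", "O", "E", "PY", "sir"))
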