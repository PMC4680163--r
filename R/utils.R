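`%||%` <- function(a, b) if (is.null(a)) b else a

# silence R CMD check notes for NSE column names used in dplyr/tidyr verbs
utils::globalVariables(c(
  "method", "observer", "session", "scan_id", "volume_cm3", "value",
  "true_volume_cm3", "shape_class", "size_cat", "abc2", "modified_abc2",
  "sas", "avc", "A_cm", "B_cm", "C_cm", "diff_abc2", "m", "d",
  "area_cm2", "thickness_mm", "slice"
))
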