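# builders for hand-crafted records and flag frames

record <- function(patient_id = "p1", age_years = 40, ...) {
  validate_record(c(list(patient_id = patient_id, age_years = age_years),
                    list(...)))
}

# an all-FALSE flag frame over the default triggers, for engine-level tests
flag_frame <- function(n = 1, ...) {
  wt <- default_weight_table()
  fl <- as.data.frame(matrix(FALSE, n, length(unique(wt$trigger)),
                             dimnames = list(NULL, unique(wt$trigger))))
  fl$patient_id <- paste0("f", seq_len(n))
  set <- list(...)
  for (v in names(set)) fl[[v]] <- set[[v]]
  fl
}

default_weights_vector <- function() {
  wt <- default_weight_table()
  stats::setNames(wt$points, wt$trigger)
}
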