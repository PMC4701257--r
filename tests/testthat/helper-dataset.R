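# One default synthetic dataset shared across test files (built on first
# use; ~3 s).
.shared <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.shared$ds))
    .shared$ds <- make_dataset(synthetic_config(seed = 1))
  .shared$ds
}

calibration_block <- function(element, ds = default_dataset()) {
  sp <- average_replicates(ds$spectra)
  align_element(sp[ds$truth$calibration_ids], ds$reference, element)
}
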