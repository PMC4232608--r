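# Shared test helpers: presets with selected parameters overridden, and
# fully deterministic (noise- and variability-free) variants.

modify_preset <- function(p, ...) {
  over <- list(...)
  p$params[names(over)] <- over
  p
}

det_nucleus_preset <- function(name = "wt_loaded", ...) {
  modify_preset(preset("nucleus", name), cap_cv = 0, photon_cv = 0, ...)
}

withr_local_tempdir <- function() {
  d <- tempfile("ercdyn-test-")
  dir.create(d)
  d
}
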