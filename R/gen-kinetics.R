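#' Construct a fluorescence trace
#'
#' Time-stamped ROI fluorescence series from a FLIP or FRAP experiment.
#'
#' @param t Acquisition times (s), strictly increasing.
#' @param I Intensities (A.U., non-negative).
#' @param roi ROI label: one of `"mother"`, `"bud"`, `"circle-adjacent"`,
#'   `"opposite"`, `"whole-nucleus"`.
#' @param bleach_times Times at which the bleach pulse was applied; must
#'   fall inside the acquisition window.
#' @param normalized Has the trace been loss-corrected and normalized?
#' @return A `fluor_trace` object.
#' @export
new_fluor_trace <- function(t, I, roi = "whole-nucleus",
                            bleach_times = numeric(), normalized = FALSE) {
  if (length(t) != length(I))
    abort_input("t and I must have the same length")
  if (any(diff(t) <= 0)) abort_input("time base must be strictly increasing")
  if (any(I < 0)) abort_input("intensities must be non-negative")
  if (length(bleach_times) &&
      (min(bleach_times) < min(t) - 1e-9 || max(bleach_times) > max(t) + 1e-9))
    abort_input("bleach_times must fall inside the acquisition window")
  structure(list(t = t, I = I, roi = roi, bleach_times = bleach_times,
                 normalized = normalized),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> roi = %s, %d points over %.1f s%s\n",
              x$roi, length(x$t), diff(range(x$t)),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Simulate a FLIP experiment (pair of repeatedly bleached ROI traces)
#'
#' Repeated photobleaching at fixed intervals; each ROI follows a
#' two-pool model: a mobile pool exchanging with the bleached region
#' decays as `exp(-k t)` while an immobile fraction keeps its
#' fluorescence.  An additive per-frame acquisition loss
#' (`acq_loss_per_frame`, A.U.) can be switched on; it is what
#' [correct_acquisition_loss()] removes using neighbor traces.
#'
#' The two traces use `k_mother`/`k_bud` when the preset defines them
#' (bud-neck barrier assay; ROIs `"mother"`/`"bud"`), else `k_decay`
#' (and optionally `k_decay_b`) with ROIs `"circle-adjacent"` /
#' `"opposite"`.
#'
#' @param preset A `"flip"` family [preset()].
#' @param seed Seed; defaults to the preset's.
#' @param noiseless If `TRUE`, omit measurement noise.
#' @return Named list of two [new_fluor_trace()] objects (`a`, `b`) with
#'   `normalized = FALSE`.
#' @examples
#' fl <- gen_flip_series(preset("flip", "circle_adjacent"), noiseless = TRUE)
#' time_to_fraction(fit_exponential_decay(fl$a), 0.7)
#' @export
gen_flip_series <- function(preset, seed = preset$seed, noiseless = FALSE) {
  stopifnot(inherits(preset, "generator_preset"))
  p <- preset$params
  if (!is.null(p$k_mother)) {
    ks <- c(p$k_mother, p$k_bud)
    rois <- c("mother", "bud")
  } else {
    ks <- c(p$k_decay, p$k_decay_b %||% p$k_decay)
    rois <- c("circle-adjacent", "opposite")
  }
  if (any(ks <= 0)) abort_input("decay rates must be strictly positive")
  tt <- (seq_len(p$n_points) - 1L) * p$interval_s
  imm <- p$immobile_frac
  out <- lapply(1:2, function(j) {
    I <- p$I0 * (imm + (1 - imm) * exp(-ks[j] * tt))
    I <- I - p$acq_loss_per_frame * (seq_along(tt) - 1L)
    if (!noiseless && p$noise_sd > 0)
      I <- I + with_seed(derive_seed(seed, paste0("flip", j)),
                         stats::rnorm(length(tt), 0, p$noise_sd))
    new_fluor_trace(tt, pmax(I, 0), roi = rois[j], bleach_times = tt,
                    normalized = FALSE)
  })
  names(out) <- c("a", "b")
  out
}

#' Simulate a FRAP recovery trace
#'
#' Bleach of the whole bud compartment at t = 0 followed by one-phase
#' association recovery `I(t) = plateau * (1 - exp(-k t))` plus optional
#' Gaussian noise and additive acquisition loss.
#'
#' @param preset A `"frap"` family [preset()] with `k` (s^-1) and
#'   `plateau` (percent of pre-bleach, in (0, 100]).
#' @param seed Seed; defaults to the preset's.
#' @param noiseless If `TRUE`, omit measurement noise.
#' @return A [new_fluor_trace()] (ROI `"bud"`) starting at I(0) = 0.
#' @export
gen_frap_series <- function(preset, seed = preset$seed, noiseless = FALSE) {
  stopifnot(inherits(preset, "generator_preset"))
  p <- preset$params
  if (p$plateau <= 0 || p$plateau > 100)
    abort_input("plateau must lie in (0, 100]")
  if (p$k <= 0) abort_input("recovery rate k must be strictly positive")
  tt <- (seq_len(p$n_points) - 1L) * p$interval_s
  I <- p$plateau * (1 - exp(-p$k * tt))
  if (!noiseless && p$noise_sd > 0)
    I <- I + with_seed(derive_seed(seed, "frap"),
                       stats::rnorm(length(tt), 0, p$noise_sd))
  new_fluor_trace(tt, pmax(I, 0), roi = "bud", bleach_times = 0,
                  normalized = FALSE)
}
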