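#' Simulate nuclear-rim intensity profiles (green NPC + red plasmid)
#'
#' Emulates intensity traces measured along the nuclear envelope in
#' equatorial sections of cells carrying a single labelled DNA circle at
#' the rim.  The green (NPC reporter) channel is a flat baseline plus a
#' local enrichment bump centred on the plasmid position plus AR(1)
#' correlated noise; the red channel is a Gaussian peak at the plasmid.
#' The bump is a truncated Gaussian confined to the co-localization
#' window (`+/- window_um` of arc) and scaled so that the mean uplift
#' inside the window equals `amplitude` exactly: a noiseless profile
#' therefore yields an enrichment of `100 * amplitude` percent from
#' [align_and_average_profiles()].
#'
#' Channels are normalized as measured in practice: green by its
#' per-cell mean (mean exactly 1), red by its per-cell maximum.
#'
#' @param preset A `"rim"` family [preset()].
#' @param n_cells Number of profiles.
#' @param seed Seed; defaults to the preset's.
#' @param noiseless If `TRUE`, omit both channels' noise.
#' @return List of `rim_profile` objects: each has `s` (arc positions,
#'   um), `green`, `red`, `peak_index` (red-channel argmax) and a
#'   `truth` block with the generating amplitude and plasmid index.
#' @examples
#' prof <- gen_rim_profiles(preset("rim", "wt"), 5)
#' align_and_average_profiles(prof)$enrichment_pct
#' @export
gen_rim_profiles <- function(preset, n_cells, seed = preset$seed,
                             noiseless = FALSE) {
  stopifnot(inherits(preset, "generator_preset"))
  p <- preset$params
  if (p$step_um > 0.065)
    abort_input("arc sampling step must be <= 0.065 um (half the 130 nm window)")
  lapply(seq_len(n_cells), function(i) {
    gen_rim_profile_one(p, derive_seed(seed, paste0("rim", i)), noiseless)
  })
}

gen_rim_profile_one <- function(p, seed, noiseless) {
  with_seed(seed, {
    L <- round(2 * pi * p$radius_um / p$step_um)
    s <- (seq_len(L) - 1L) * p$step_um
    circumference <- L * p$step_um
    idx0 <- sample.int(L, 1)
    d <- circular_arc_distance(s, s[idx0], circumference)
    in_window <- d <= p$window_um + 1e-12

    bump <- exp(-d^2 / (2 * p$bump_sd_um^2))
    bump[!in_window] <- 0
    bump <- bump * (p$amplitude / mean(bump[in_window]))

    green <- 1 + bump
    red <- exp(-d^2 / (2 * p$red_peak_sd_um^2))
    if (!noiseless) {
      green <- green + ar1_noise(L, p$noise_sd, p$noise_ar)
      red <- red + stats::rnorm(L, 0, p$red_noise_sd)
    }
    green <- pmax(green, 0)
    red <- pmax(red, 0)
    new_rim_profile(s, green, red,
                    truth = list(amplitude = p$amplitude, plasmid_index = idx0,
                                 window_um = p$window_um))
  })
}

#' Construct a rim profile
#'
#' Applies the channel normalizations used throughout: green divided by
#' its mean (so `mean(green) == 1`), red divided by its maximum.
#'
#' @param s Arc positions (um), uniformly spaced along the rim circle.
#' @param green,red Channel intensities (same length as `s`).
#' @param truth Optional generating metadata.
#' @return A `rim_profile` object with `peak_index = which.max(red)`.
#' @export
new_rim_profile <- function(s, green, red, truth = NULL) {
  stopifnot(length(s) == length(green), length(s) == length(red))
  if (any(green < 0) || any(red < 0))
    abort_input("rim profile intensities must be non-negative")
  green <- green / mean(green)
  red <- red / max(red)
  structure(list(s = s, green = green, red = red,
                 peak_index = which.max(red), truth = truth),
            class = "rim_profile")
}

# stationary AR(1) noise with innovation scaled to marginal SD `sd`
ar1_noise <- function(n, sd, phi) {
  if (sd <= 0) return(numeric(n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.vector(stats::filter(e, phi, method = "recursive", init = stats::rnorm(1, 0, sd)))
}

circular_arc_distance <- function(s, ref, circumference) {
  d <- abs(s - ref)
  pmin(d, circumference - d)
}
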