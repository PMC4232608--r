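#' Simulate a 2-D nucleus image with an NPC cap and plasmid focus
#'
#' Draws an equatorial section of a yeast nucleus as a fluorescent rim
#' (the NPC reporter): a circular annulus blurred radially with a
#' Gaussian profile of SD `psf_sd_um` (truncated at `trunc_sd` SDs).  In
#' a circle-loaded cell the rim intensity inside an angular cap of width
#' `cap_span` centred on the plasmid equals `cap_ratio` times the rest
#' of the rim, and a second (red) channel carries the plasmid focus at
#' the cap centre.  The blur is applied along the radius only, so the
#' angular cap edges stay sharp and sector mean intensities of the
#' noiseless image recover the generating ratio exactly.
#'
#' Optional noise is Poisson shot noise (scaled by `gain`) on signal
#' plus background, followed by additive Gaussian read noise of SD
#' `read_sd`; negative values are clipped to zero.  Per-cell biological
#' variability enters through lognormal draws of the cap ratio
#' (`cap_cv`) and the photon budget (`photon_cv`).
#'
#' @param preset A `"nucleus"` family [preset()].
#' @param loaded Logical: does the cell carry an accumulated circle
#'   cluster (cap + focus)?
#' @param seed Seed; defaults to the preset's.
#' @param noiseless If `TRUE`, skip pixel noise (per-cell variability is
#'   still governed by `cap_cv`/`photon_cv`; set those to 0 for a fully
#'   deterministic image).
#' @return A `nucleus_image`: list with `pixels` (green channel matrix),
#'   `red` (plasmid channel matrix or `NULL`), `pixel_size`, and a
#'   `truth` block recording every generating value, including
#'   `total_signal`, the exact photon count placed in the green channel.
#' @examples
#' img <- gen_nucleus_image(preset("nucleus", "wt_loaded"), loaded = TRUE)
#' dim(img$pixels)
#' @export
gen_nucleus_image <- function(preset, loaded = TRUE, seed = preset$seed,
                              noiseless = FALSE) {
  stopifnot(inherits(preset, "generator_preset"))
  p <- preset$params
  if (p$cap_span <= 0 || p$cap_span >= 2 * pi)
    abort_input("cap_span must lie strictly between 0 and 2*pi")
  if (p$cap_ratio < 1) abort_input("cap_ratio must be >= 1")
  n <- p$img_px
  half_extent <- n * p$pixel_size / 2
  if (p$radius_um >= half_extent)
    abort_input("rim radius must be smaller than half the image extent")

  with_seed(seed, {
    cap_ratio <- if (loaded && p$cap_cv > 0) {
      rlnorm_mean_cv(1, p$cap_ratio, p$cap_cv)
    } else if (loaded) p$cap_ratio else 1.0
    photons <- if (p$photon_cv > 0) {
      rlnorm_mean_cv(1, p$total_photons, p$photon_cv)
    } else p$total_photons
    plasmid_angle <- stats::runif(1, 0, 2 * pi)

    geo <- pixel_geometry(n, p$pixel_size)
    radial <- annulus_profile(geo$r, p$radius_um, p$psf_sd_um, p$trunc_sd)
    ang <- rep(1, length(geo$theta))
    if (loaded)
      ang[angular_distance(geo$theta, plasmid_angle) <= p$cap_span / 2] <- cap_ratio
    signal <- radial * ang
    signal <- signal * (photons / sum(signal))
    signal <- matrix(signal, n, n)

    pixels <- signal + p$background
    if (!noiseless) {
      shot <- p$gain * matrix(stats::rpois(n * n, pixels / p$gain), n, n)
      pixels <- shot + matrix(stats::rnorm(n * n, 0, p$read_sd), n, n)
      pixels[pixels < 0] <- 0
    }

    red <- NULL
    if (loaded) {
      fx <- geo$cx + (p$radius_um / p$pixel_size) * cos(plasmid_angle)
      fy <- geo$cy + (p$radius_um / p$pixel_size) * sin(plasmid_angle)
      d2 <- (geo$px - fx)^2 + (geo$py - fy)^2
      focus <- exp(-d2 * (p$pixel_size^2) / (2 * p$focus_sd_um^2))
      focus <- focus * (p$focus_photons / sum(focus))
      red <- matrix(focus + p$background, n, n)
      if (!noiseless) {
        red <- matrix(stats::rpois(n * n, red / p$gain) * p$gain, n, n) +
          matrix(stats::rnorm(n * n, 0, p$read_sd), n, n)
        red[red < 0] <- 0
      }
    }

    structure(list(
      pixels = pixels, red = red, pixel_size = p$pixel_size,
      truth = list(center_px = c(geo$cx, geo$cy), radius_um = p$radius_um,
                   psf_sd_um = p$psf_sd_um, trunc_sd = p$trunc_sd,
                   cap_ratio = cap_ratio, cap_span = p$cap_span,
                   plasmid_angle = if (loaded) plasmid_angle else NA_real_,
                   background = p$background,
                   total_signal = sum(signal), loaded = loaded)),
      class = "nucleus_image")
  })
}

#' Simulate a cohort of nucleus images
#'
#' @inheritParams gen_nucleus_image
#' @param n_cells Number of images.
#' @return List of `nucleus_image` objects with per-cell derived seeds.
#' @export
gen_nucleus_cohort <- function(preset, n_cells, loaded = TRUE,
                               seed = preset$seed, noiseless = FALSE) {
  lapply(seq_len(n_cells), function(i)
    gen_nucleus_image(preset, loaded = loaded,
                      seed = derive_seed(seed, paste0("nucleus", i)),
                      noiseless = noiseless))
}

# lognormal with given arithmetic mean and coefficient of variation
rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# pixel-centre coordinates: 0-based, centre of the image at ((n-1)/2)
pixel_geometry <- function(n, pixel_size) {
  cx <- (n - 1) / 2
  cy <- (n - 1) / 2
  px <- matrix(rep(0:(n - 1), each = n), n, n)   # column index per pixel
  py <- matrix(rep(0:(n - 1), times = n), n, n)  # row index per pixel
  dx <- (px - cx) * pixel_size
  dy <- (py - cy) * pixel_size
  list(cx = cx, cy = cy, px = px, py = py,
       r = sqrt(dx^2 + dy^2), theta = atan2(dy, dx) %% (2 * pi))
}

# truncated radial Gaussian annulus profile
annulus_profile <- function(r, radius, sd, trunc_sd) {
  out <- exp(-(r - radius)^2 / (2 * sd^2))
  out[abs(r - radius) > trunc_sd * sd] <- 0
  out
}

angular_distance <- function(theta, ref) {
  d <- abs((theta - ref) %% (2 * pi))
  pmin(d, 2 * pi - d)
}
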