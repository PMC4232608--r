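#' Simulate confined 3-D plasmid diffusion tracks
#'
#' Isotropic Gaussian random walk: per-axis step SD `step_sd_um` per
#' `dt_s` interval, reflected at a spherical confinement boundary of
#' radius `confine_um` (0 disables confinement).  The unconfined mean
#' 3-D step length is `step_sd_um * 2 * sqrt(2/pi) * sqrt(...)` — the
#' mean of a chi distribution with 3 degrees of freedom,
#' `step_sd_um * sqrt(2) * gamma(2) / gamma(3/2)` (about
#' `1.5958 * step_sd_um`), so the preset step SDs encode the published
#' mean speeds via `speed = E|step| / dt`.
#'
#' @param preset A `"tracks"` family [preset()].
#' @param n_tracks Number of tracks.
#' @param seed Seed; defaults to the preset's.
#' @return List of `track` objects: each a list with `t` (s) and `xyz`
#'   (n x 3 matrix, um).
#' @examples
#' tr <- gen_tracks(preset("tracks", "wt"), 3)
#' mean(vapply(tr, track_speed, numeric(1)))
#' @export
gen_tracks <- function(preset, n_tracks, seed = preset$seed) {
  stopifnot(inherits(preset, "generator_preset"))
  p <- preset$params
  if (p$step_sd_um <= 0) abort_input("step_sd_um must be strictly positive")
  lapply(seq_len(n_tracks), function(i)
    gen_track_one(p, derive_seed(seed, paste0("track", i))))
}

gen_track_one <- function(p, seed) {
  with_seed(seed, {
    n <- p$n_points
    xyz <- matrix(0, n, 3)
    R <- p$confine_um
    # start uniformly inside the confinement sphere (or at the origin)
    if (R > 0) {
      repeat {
        x0 <- stats::runif(3, -R, R)
        if (sum(x0^2) <= R^2) break
      }
      xyz[1, ] <- x0
    }
    steps <- matrix(stats::rnorm(3 * (n - 1), 0, p$step_sd_um), n - 1, 3)
    for (i in 2:n) {
      pos <- xyz[i - 1, ] + steps[i - 1, ]
      if (R > 0) pos <- reflect_into_sphere(pos, R)
      xyz[i, ] <- pos
    }
    structure(list(t = (seq_len(n) - 1L) * p$dt_s, xyz = xyz,
                   truth = list(step_sd_um = p$step_sd_um,
                                confine_um = p$confine_um)),
              class = "track")
  })
}

# radial reflection at a sphere of radius R (repeated until inside)
reflect_into_sphere <- function(pos, R) {
  for (iter in 1:32) {
    r <- sqrt(sum(pos^2))
    if (r <= R) return(pos)
    pos <- pos * (2 * R - r) / r
  }
  pos * (R / sqrt(sum(pos^2)))  # pathological step; clamp to the boundary
}
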