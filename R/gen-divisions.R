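#' Simulate telophase division records (mother/bud fluorescence)
#'
#' Emulates the per-division quantification of NPC reporter fluorescence
#' in mother and bud nuclei at the end of nuclear division.  The
#' mother's share of the total fluorescence is drawn logit-normally with
#' the preset's median (`pct_mother_median`, percent) and spread
#' (`logit_sd`); the per-division total is lognormal around
#' `total_mean`.  Nuclear areas scale with the fluorescence share.
#'
#' @param preset A `"division"` family [preset()].
#' @param n_divisions Number of telophase records.
#' @param seed Seed; defaults to the preset's.
#' @return A data frame (`division_records`) with columns `mother_total`,
#'   `bud_total`, `mother_area`, `bud_area`, `age`, `preset`.
#' @examples
#' rec <- gen_division_records(preset("division", "wt_loaded"), 50)
#' stats::median(percent_to_mother(rec))
#' @export
gen_division_records <- function(preset, n_divisions, seed = preset$seed) {
  stopifnot(inherits(preset, "generator_preset"))
  if (n_divisions < 1) abort_input("n_divisions must be >= 1")
  p <- preset$params
  med <- p$pct_mother_median / 100
  if (med <= 0 || med >= 1)
    abort_input("pct_mother_median must lie strictly between 0 and 100")
  with_seed(seed, {
    share <- stats::plogis(stats::rnorm(n_divisions, stats::qlogis(med),
                                        p$logit_sd))
    total <- rlnorm_mean_cv(n_divisions, p$total_mean, p$total_cv)
    area_total <- 4 + 2 * stats::runif(n_divisions)  # um^2, sum projection
    out <- data.frame(
      mother_total = share * total,
      bud_total = (1 - share) * total,
      mother_area = share * area_total,
      bud_area = (1 - share) * area_total,
      age = sample.int(p$max_age, n_divisions, replace = TRUE),
      preset = preset$name,
      stringsAsFactors = FALSE)
    class(out) <- c("division_records", class(out))
    out
  })
}
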