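#' Simulate a mother-daughter pedigree marker table
#'
#' Emulates dissecting daughters off mothers that carry `k_circles`
#' marked ERCs: each circle propagates to the daughter independently
#' with probability `p_prop`, so the daughter carries the marker iff at
#' least one circle propagates (probability `1 - (1 - p_prop)^k`).
#'
#' @param preset A `"pedigree"` family [preset()] with `k_circles` and
#'   `p_prop`.
#' @param n_mothers Number of mother-daughter pairs.
#' @param seed Seed; defaults to the preset's.
#' @return Data frame (`pedigree_table`) with columns `mother_id`,
#'   `mother_circle_count`, `daughter_has_marker`.
#' @examples
#' tab <- gen_pedigree_table(preset("pedigree", "wt"), 1000)
#' pedigree_retention_frequency(tab)  # ~ 100 * 0.961^24
#' @export
gen_pedigree_table <- function(preset, n_mothers, seed = preset$seed) {
  stopifnot(inherits(preset, "generator_preset"))
  p <- preset$params
  k <- p$k_circles
  if (k < 1) abort_input("k_circles must be >= 1")
  with_seed(seed, {
    has_marker <- stats::runif(n_mothers) < 1 - (1 - p$p_prop)^k
    out <- data.frame(mother_id = seq_len(n_mothers),
                      mother_circle_count = rep(as.integer(k), n_mothers),
                      daughter_has_marker = has_marker)
    class(out) <- c("pedigree_table", class(out))
    out
  })
}

#' Simulate a half-sectored colony assay
#'
#' Scores marker excision within the rDNA array: a colony is
#' half-sectored iff the marker is excised before the first division
#' (probability `p_excise`) and the excised circle is then lost from one
#' of the two first-division lineages (probability `p_first_loss`);
#' other excision outcomes yield irregular ("other") sectoring.
#'
#' @param preset A `"sectors"` family [preset()].
#' @param n_colonies Number of colonies plated.
#' @param seed Seed; defaults to the preset's.
#' @return Data frame (`colony_table`) with columns `colony_id` and
#'   `sector_class` (factor: `half`, `other`, `none`).
#' @export
gen_sector_colonies <- function(preset, n_colonies, seed = preset$seed) {
  stopifnot(inherits(preset, "generator_preset"))
  p <- preset$params
  with_seed(seed, {
    excised <- stats::runif(n_colonies) < p$p_excise
    first_loss <- stats::runif(n_colonies) < p$p_first_loss
    cls <- ifelse(excised & first_loss, "half",
                  ifelse(excised, "other", "none"))
    out <- data.frame(colony_id = seq_len(n_colonies),
                      sector_class = factor(cls, levels = c("half", "other", "none")))
    class(out) <- c("colony_table", class(out))
    out
  })
}
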