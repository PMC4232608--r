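#' Propagation frequency (pf) of DNA circles from a telophase tally
#'
#' Estimates the percentage of plasmids passed to the bud per division
#' from the fraction of 1-, 2- and 4-plasmid telophase cells retaining
#' all their plasmids in the mother (`a`, `b`, `c` percent, counted over
#' `x`, `y`, `z` cells).
#'
#' The `"consistent"` variant (default) converts each category to a
#' per-plasmid retention percentage before averaging,
#' `R1 = a`, `R2 = 100 * sqrt(b/100)`, `R4 = 100 * (c/100)^(1/4)`, and
#' returns `pf = 100 - (x*R1 + 2*y*R2 + 4*z*R4) / (x + 2*y + 4*z)`.
#' Under independent per-plasmid propagation with probability p this
#' makes pf a consistent estimate of `100 p`.  The `"as_printed"`
#' variant evaluates the assay formula literally,
#' `pf = 100 - (x*a + 2*y*sqrt(b) + 4*z*c^(1/4)) / (x + 2*y + 4*z)`,
#' where the root terms are taken on the 0-100 percentage scale; it is
#' retained for transparency.  Because the roots of a 0-100 percentage
#' land on 0-10 (square root) and 0-3.2 (fourth root) scales, the
#' literal formula disagrees with the consistent variant whenever multi-
#' plasmid cells are scored — even at full retention.
#'
#' @param counts A [new_segregation_counts()] object.
#' @param variant `"consistent"` or `"as_printed"`.
#' @return A `pf_result`: list with `pf` (percent), `variant`,
#'   `per_plasmid_retention` (fraction, `1 - pf/100`) and `n_effective`
#'   (`x + 2y + 4z` plasmids).
#' @examples
#' counts <- new_segregation_counts(x = 61, y = 33, z = 6,
#'                                  a = 90, b = 81, c = 65.61)
#' compute_pf(counts)$pf  # ~10
#' @export
compute_pf <- function(counts, variant = c("consistent", "as_printed")) {
  stopifnot(inherits(counts, "segregation_counts"))
  variant <- match.arg(variant)
  n <- c(counts$x, counts$y, counts$z)
  pct <- c(counts$a, counts$b, counts$c)
  w <- c(1, 2, 4)
  n_eff <- as.integer(sum(w * n))
  if (n_eff <= 0) abort_input("x + 2y + 4z must be positive")
  if (any(n > 0 & is.na(pct)))
    abort_input("a nonzero category has an undefined retaining percentage")
  if (any(!is.na(pct) & pct < 0))
    abort_input("retaining percentages must be non-negative")
  pct0 <- ifelse(is.na(pct), 0, pct)  # empty categories carry zero weight
  R <- switch(variant,
    consistent = 100 * (pct0 / 100)^(1 / w),
    as_printed = pct0^(1 / w))
  pf <- 100 - sum(w * n * R) / n_eff
  structure(list(pf = pf, variant = variant,
                 per_plasmid_retention = 1 - pf / 100,
                 n_effective = n_eff),
            class = "pf_result")
}

#' @export
print.pf_result <- function(x, ...) {
  cat(sprintf("pf = %.2f%% (%s variant, n_effective = %d plasmids)\n",
              x$pf, x$variant, x$n_effective))
  invisible(x)
}

#' Pedigree retention frequency
#'
#' Percentage of mothers whose daughter lacks the ERC marker, i.e. for
#' which every accumulated circle remained in the mother.
#'
#' @param table A [gen_pedigree_table()]-style data frame with a logical
#'   `daughter_has_marker` column.
#' @return Percentage in `[0, 100]`.
#' @export
pedigree_retention_frequency <- function(table) {
  if (!"daughter_has_marker" %in% names(table))
    abort_input("pedigree table must have a 'daughter_has_marker' column")
  if (nrow(table) == 0) abort_input("pedigree table is empty")
  100 * mean(!table$daughter_has_marker)
}

#' Half-sectored colony rate
#'
#' Rate of ERC-formation events scored as half-sectored colonies over
#' all colonies; exact rational on integer inputs.
#'
#' @param table A [gen_sector_colonies()]-style data frame with a
#'   `sector_class` column, or a list/data frame convertible to one.
#' @return Fraction of colonies that are half-sectored.
#' @export
half_sector_rate <- function(table) {
  if (!"sector_class" %in% names(table))
    abort_input("colony table must have a 'sector_class' column")
  if (nrow(table) == 0) abort_input("colony table is empty")
  sum(table$sector_class == "half") / nrow(table)
}

#' ChIP fold enrichment
#'
#' `fold = (ip/input) / (ip_ctrl/input_ctrl)`: the IP/Input ratio of the
#' tagged strain normalized by the same ratio in the untagged control,
#' correcting for unspecific binding.  Vectorized over loci; names are
#' carried through.
#'
#' @param ip,input IP and input signals of the tagged strain (> 0).
#' @param ip_ctrl,input_ctrl Same signals in the untagged control (> 0).
#' @return A `chip_enrichment`: named numeric vector of fold ratios.
#' @examples
#' chip_fold_enrichment(ip = 10, input = 2, ip_ctrl = 1, input_ctrl = 2)
#' @export
chip_fold_enrichment <- function(ip, input, ip_ctrl, input_ctrl) {
  sig <- cbind(ip, input, ip_ctrl, input_ctrl)
  if (any(!is.finite(sig)) || any(sig <= 0))
    abort_input("all ChIP signals must be finite and strictly positive")
  fold <- (ip / input) / (ip_ctrl / input_ctrl)
  structure(fold, class = c("chip_enrichment", class(fold)))
}

#' Compare measurement groups (ANOVA + Dunnett, or t-test)
#'
#' The comparison machinery of the study's figure statistics: one-way
#' ANOVA followed by Dunnett's multiple comparison against a reference
#' group, or an unpaired two-tailed t-test for two groups.
#'
#' @param values Numeric measurements.
#' @param group Group labels (coerced to factor), same length as
#'   `values`; each group needs n >= 2.
#' @param design `"anova_dunnett"` or `"t_test"` (the latter requires
#'   exactly two groups).
#' @param reference Reference (control) group for Dunnett; defaults to
#'   the first factor level.
#' @return A `group_comparison`: list with `design`, `statistic`, `df`,
#'   `p_value` (omnibus for ANOVA), `comparisons` (data frame of
#'   per-group adjusted p-values for Dunnett), and `degenerate` flag
#'   (all groups constant: no p-value is fabricated).
#' @export
compare_groups <- function(values, group,
                           design = c("anova_dunnett", "t_test"),
                           reference = NULL) {
  design <- match.arg(design)
  group <- droplevels(as.factor(group))
  if (length(values) != length(group))
    abort_input("values and group must have the same length")
  if (nlevels(group) < 2) abort_input("need at least 2 groups")
  if (any(table(group) < 2)) abort_input("each group needs n >= 2")
  if (!is.null(reference)) group <- stats::relevel(group, ref = reference)

  if (all(tapply(values, group, stats::var) == 0)) {
    return(structure(list(design = design, statistic = NA_real_,
                          df = NA_real_, p_value = NA_real_,
                          comparisons = NULL, degenerate = TRUE),
                     class = "group_comparison"))
  }

  if (design == "t_test") {
    if (nlevels(group) != 2) abort_input("t_test requires exactly 2 groups")
    tt <- stats::t.test(values ~ group, var.equal = FALSE)
    out <- list(design = design, statistic = unname(tt$statistic),
                df = unname(tt$parameter), p_value = tt$p.value,
                comparisons = NULL, degenerate = FALSE)
  } else {
    dat <- data.frame(values = values, group = group)
    fit <- stats::aov(values ~ group, data = dat)
    an <- summary(fit)[[1]]
    dn <- summary(multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett")))
    cmp <- data.frame(comparison = names(dn$test$coefficients),
                      estimate = unname(dn$test$coefficients),
                      p_adjusted = unname(dn$test$pvalues),
                      stringsAsFactors = FALSE)
    out <- list(design = design, statistic = an[["F value"]][1],
                df = an[["Df"]], p_value = an[["Pr(>F)"]][1],
                comparisons = cmp, degenerate = FALSE)
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat("<group_comparison> degenerate (zero variance in all groups)\n")
    return(invisible(x))
  }
  cat(sprintf("<group_comparison> %s: statistic = %.3f, p = %.3g\n",
              x$design, x$statistic, x$p_value))
  if (!is.null(x$comparisons)) print(x$comparisons, row.names = FALSE)
  invisible(x)
}
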