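#' Simulate a telophase plasmid-segregation tally
#'
#' Emulates the telophase retention assay: cells carry 1, 2 or 4 labelled
#' non-centromeric plasmids (mixing proportions `count_mix`), and each
#' plasmid propagates to the bud independently with probability
#' `p_prop`.  A cell "retains all" its plasmids iff none propagate, so
#' the expected retaining percentage in the m-plasmid category is
#' `100 * (1 - p_prop)^m`.
#'
#' @param preset A `"segregation"` family [preset()] with `p_prop` and
#'   `count_mix`.
#' @param n_cells Total number of telophase cells scored (>= 1).
#' @param seed Seed; defaults to the preset's.
#' @return A `segregation_counts` object: list with integer counts
#'   `x`, `y`, `z` (cells with 1/2/4 plasmids), observed retaining
#'   percentages `a`, `b`, `c` (`NA` for empty categories, flagged in
#'   `undefined`), and the generating parameters.
#' @examples
#' counts <- gen_segregation_counts(preset("segregation", "wt"), 5000)
#' compute_pf(counts)
#' @export
gen_segregation_counts <- function(preset, n_cells, seed = preset$seed) {
  stopifnot(inherits(preset, "generator_preset"))
  if (n_cells < 1) abort_input("n_cells must be >= 1")
  p <- preset$params$p_prop
  mix <- preset$params$count_mix
  stopifnot(length(mix) == 3L)
  with_seed(seed, {
    n <- as.vector(stats::rmultinom(1, size = n_cells, prob = mix))
    m <- c(1L, 2L, 4L)
    kept <- vapply(seq_along(m), function(i) {
      if (n[i] == 0L) return(NA_integer_)
      stats::rbinom(1L, n[i], (1 - p)^m[i])
    }, integer(1))
    pct <- ifelse(is.na(kept), NA_real_, 100 * kept / n)
    new_segregation_counts(x = n[1], y = n[2], z = n[3],
                           a = pct[1], b = pct[2], c = pct[3],
                           p_prop = p, seed = seed)
  })
}

#' Construct a telophase tally by hand
#'
#' @param x,y,z Cell counts for the 1-, 2- and 4-plasmid categories.
#' @param a,b,c Percentage of each category retaining all plasmids in
#'   the mother (`NA` allowed only when the matching count is 0).
#' @param p_prop,seed Optional generating metadata.
#' @return A `segregation_counts` object.
#' @export
new_segregation_counts <- function(x, y, z, a, b, c,
                                   p_prop = NA_real_, seed = NA_integer_) {
  counts <- c(x = x, y = y, z = z)
  pct <- c(a = a, b = b, c = c)
  if (any(counts < 0)) abort_input("cell counts must be non-negative")
  if (any(!is.na(pct) & (pct < 0 | pct > 100)))
    abort_input("retaining percentages must lie in [0, 100]")
  structure(list(x = as.integer(x), y = as.integer(y), z = as.integer(z),
                 a = a, b = b, c = c,
                 undefined = names(pct)[is.na(pct)],
                 p_prop = p_prop, seed = seed),
            class = "segregation_counts")
}

#' @export
print.segregation_counts <- function(x, ...) {
  cat("<segregation_counts>\n")
  cat(sprintf("  1-plasmid: n = %d, retained all = %s%%\n", x$x, fmt_pct(x$a)))
  cat(sprintf("  2-plasmid: n = %d, retained all = %s%%\n", x$y, fmt_pct(x$b)))
  cat(sprintf("  4-plasmid: n = %d, retained all = %s%%\n", x$z, fmt_pct(x$c)))
  invisible(x)
}

fmt_pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f", v)
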