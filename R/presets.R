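#' Generator presets
#'
#' A `generator_preset` bundles the named parameters of one synthetic-data
#' generator together with the seed that makes it deterministic.  The
#' shipped registry (`inst/extdata/presets.yaml`) holds one preset per
#' genotype and assay: per-plasmid propagation probabilities for the
#' telophase segregation assay, cap ratios and photon budgets for the
#' nucleus images, enrichment amplitudes for the rim profiles, decay and
#' recovery rates for the photobleaching traces, step SDs for the
#' plasmid tracks, and retention/formation parameters for the ageing
#' simulator.
#'
#' @param name Preset name (free text, used in reports).
#' @param params Named list of numeric (or numeric-vector) parameters.
#' @param seed Integer seed; generators default to it.
#' @return An object of class `generator_preset`.
#' @examples
#' p <- preset("segregation", "wt")
#' p$params$p_prop
#' @export
new_preset <- function(name, params, seed = 1L) {
  stopifnot(is.character(name), length(name) == 1L, is.list(params))
  if (!length(seed) == 1L || !is.finite(seed))
    abort_input("preset seed must be a single finite integer")
  validate_preset_params(params)
  structure(list(name = name, params = params, seed = as.integer(seed)),
            class = "generator_preset")
}

# Probabilities must lie in [0,1]; mixing proportions must sum to 1;
# rates, lengths and counts must be strictly positive.
validate_preset_params <- function(params) {
  prob_names <- c("p_prop", "rho", "immobile_frac", "fidelity", "s0",
                  "f_form", "p_excise", "p_first_loss", "noise_ar")
  for (nm in intersect(names(params), prob_names)) {
    v <- params[[nm]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      abort_input(sprintf("parameter '%s' must lie in [0, 1]", nm))
  }
  if (!is.null(params$count_mix)) {
    cm <- params$count_mix
    if (any(cm < 0) || abs(sum(cm) - 1) > 1e-9)
      abort_input("count_mix proportions must be non-negative and sum to 1")
  }
  pos_names <- c("k_decay", "k", "k_mother", "k_bud", "pixel_size",
                 "radius_um", "psf_sd_um", "step_um", "step_sd_um",
                 "dt_s", "interval_s", "T_death", "total_photons",
                 "npc0", "total_mean")
  for (nm in intersect(names(params), pos_names)) {
    v <- params[[nm]]
    if (any(!is.finite(v)) || any(v <= 0))
      abort_input(sprintf("parameter '%s' must be strictly positive", nm))
  }
  invisible(params)
}

#' @export
print.generator_preset <- function(x, ...) {
  cat("<generator_preset>", x$name, " (seed ", x$seed, ")\n", sep = "")
  flat <- vapply(x$params, function(v) paste(signif(unlist(v), 6), collapse = ", "),
                 character(1))
  cat(paste0("  ", format(names(flat)), " : ", flat, collapse = "\n"), "\n")
  invisible(x)
}

# Registry cache
the <- new.env(parent = emptyenv())

#' Load the preset registry
#'
#' @param path Path to a YAML registry; defaults to the registry shipped
#'   with the package.
#' @return Nested list of preset families.
#' @export
load_presets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "presets.yaml", package = "ercdyn",
                        mustWork = TRUE)
  reg <- yaml::read_yaml(path)
  reg$schema_version <- NULL
  reg
}

preset_registry <- function() {
  if (is.null(the$registry)) the$registry <- load_presets()
  the$registry
}

#' Fetch a named preset
#'
#' Family-wide defaults (the `common` entry of a family) are merged into
#' the requested preset; explicit entries win.
#'
#' @param family Generator family, e.g. `"segregation"`, `"nucleus"`,
#'   `"division"`, `"rim"`, `"flip"`, `"frap"`, `"tracks"`,
#'   `"pedigree"`, `"sectors"`, `"ageing"`.
#' @param name Preset name within the family, e.g. `"wt"`.
#' @param seed Seed stored on the returned preset.
#' @return A [new_preset()] object.
#' @export
preset <- function(family, name, seed = 1L) {
  reg <- preset_registry()
  if (is.null(reg[[family]]))
    abort_input(sprintf("unknown preset family '%s'", family))
  fam <- reg[[family]]
  if (is.null(fam[[name]]))
    abort_input(sprintf("unknown preset '%s' in family '%s'", name, family))
  params <- fam[["common"]] %||% list()
  params[names(fam[[name]])] <- fam[[name]]
  new_preset(paste(family, name, sep = "/"), params, seed = seed)
}

#' List available presets
#'
#' @return Data frame with columns `family` and `name`.
#' @export
list_presets <- function() {
  reg <- preset_registry()
  out <- do.call(rbind, lapply(names(reg), function(f) {
    nm <- setdiff(names(reg[[f]]), "common")
    data.frame(family = f, name = nm, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
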