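#' Default end-to-end pipeline configuration
#'
#' A small demonstration configuration running every stage at modest
#' cohort sizes: telophase segregation for several genotypes, loaded and
#' unloaded nucleus cohorts, division records, rim profiles, FLIP/FRAP
#' kinetics, plasmid tracks and the ageing simulator.
#'
#' @param seed Global seed (mandatory; per-stage streams are derived
#'   from it by stable hashing of the stage name).
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed, out_dir) {
  structure(list(
    seed = as.integer(seed), out_dir = out_dir,
    stages = list(
      segregation = list(presets = c("wt", "gcn5"), n_cells = 5000),
      nuclei = list(loaded = "wt_loaded", unloaded = "unloaded", n = 25),
      divisions = list(presets = c("wt_loaded", "unloaded"), n = 50),
      rim = list(presets = c("wt", "sus1"), n = 25),
      flip = list(presets = c("circle_adjacent", "opposite")),
      frap = list(presets = c("default")),
      tracks = list(presets = c("wt", "gcn5"), n = 25),
      ageing = list(presets = c("wt", "sgf73"), n_mothers = 100))),
    class = "pipeline_config")
}

#' Run the full synthetic pipeline and write a summary report
#'
#' Executes generators, quantifiers and statistics for every configured
#' stage, writes per-stage CSVs to the output directory, and a single
#' machine-readable `summary.json` containing every headline statistic
#' (pf per genotype, Ic, percent-to-mother medians, enrichment, t70 /
#' t15, track speeds, median lifespans), each stamped with preset, seed
#' and package version.  Reruns with the same configuration are
#' byte-identical.
#'
#' @param config A [default_pipeline_config()]-style list; every
#'   referenced preset must resolve (checked before any stage runs) and
#'   the seed is mandatory.
#' @return The summary list, invisibly; files land in `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) abort_input("pipeline config needs a seed")
  if (is.null(config$out_dir)) abort_input("pipeline config needs out_dir")
  st <- config$stages
  # resolve every preset up front: a bad reference fails before any stage
  resolve <- list(segregation = "segregation", divisions = "division",
                  rim = "rim", flip = "flip", frap = "frap",
                  tracks = "tracks", ageing = "ageing")
  for (stage in names(resolve))
    for (nm in st[[stage]]$presets) preset(resolve[[stage]], nm)
  preset("nucleus", st$nuclei$loaded); preset("nucleus", st$nuclei$unloaded)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  summary <- list(seed = seed,
                  version = as.character(utils::packageVersion("ercdyn")))

  # --- segregation / pf ---
  pf_rows <- lapply(st$segregation$presets, function(nm) {
    cnt <- gen_segregation_counts(preset("segregation", nm),
                                  st$segregation$n_cells,
                                  seed = derive_seed(seed, paste0("seg/", nm)))
    res <- compute_pf(cnt)
    write_table(cnt, file.path(config$out_dir, paste0("counts_", nm, ".csv")))
    data.frame(preset = nm, pf = res$pf, variant = res$variant,
               n_effective = res$n_effective)
  })
  pf_tab <- do.call(rbind, pf_rows)
  utils::write.csv(pf_tab, file.path(config$out_dir, "pf.csv"),
                   row.names = FALSE)
  summary$pf <- stats::setNames(as.list(pf_tab$pf), pf_tab$preset)

  # --- nuclei: cap + totals ---
  loaded <- gen_nucleus_cohort(preset("nucleus", st$nuclei$loaded),
                               st$nuclei$n, loaded = TRUE,
                               seed = derive_seed(seed, "nuclei/loaded"))
  unloaded <- gen_nucleus_cohort(preset("nucleus", st$nuclei$unloaded),
                                 st$nuclei$n, loaded = FALSE,
                                 seed = derive_seed(seed, "nuclei/unloaded"))
  cq <- cap_ratio(loaded)
  tot_l <- vapply(loaded, integrated_fluorescence, numeric(1))
  tot_u <- vapply(unloaded, integrated_fluorescence, numeric(1))
  utils::write.csv(cbind(cq, total = tot_l),
                   file.path(config$out_dir, "cap_quant.csv"),
                   row.names = FALSE)
  summary$Ic_mean <- mean(cq$Ic)
  summary$total_fold_loaded_over_unloaded <-
    stats::median(tot_l) / stats::median(tot_u)

  # --- divisions ---
  summary$pct_to_mother_median <- list()
  for (nm in st$divisions$presets) {
    rec <- gen_division_records(preset("division", nm), st$divisions$n,
                                seed = derive_seed(seed, paste0("div/", nm)))
    write_table(rec, file.path(config$out_dir, paste0("divisions_", nm, ".csv")))
    summary$pct_to_mother_median[[nm]] <-
      stats::median(percent_to_mother(rec))
  }

  # --- rim enrichment ---
  summary$rim_enrichment_pct <- list()
  for (nm in st$rim$presets) {
    prof <- gen_rim_profiles(preset("rim", nm), st$rim$n,
                             seed = derive_seed(seed, paste0("rim/", nm)))
    summary$rim_enrichment_pct[[nm]] <-
      align_and_average_profiles(prof)$enrichment_pct
  }

  # --- kinetics ---
  summary$flip_t70_s <- list()
  for (nm in st$flip$presets) {
    fl <- gen_flip_series(preset("flip", nm),
                          seed = derive_seed(seed, paste0("flip/", nm)))
    fit <- fit_exponential_decay(fl$a)
    summary$flip_t70_s[[nm]] <- unname(fit$t_q[["0.7"]])
  }
  summary$frap_t15_s <- list()
  for (nm in st$frap$presets) {
    fr <- gen_frap_series(preset("frap", nm),
                          seed = derive_seed(seed, paste0("frap/", nm)))
    summary$frap_t15_s[[nm]] <- unname(fit_recovery(fr)$t_q[["t15"]])
  }

  # --- tracks ---
  summary$track_speed_um_s <- list()
  for (nm in st$tracks$presets) {
    tr <- gen_tracks(preset("tracks", nm), st$tracks$n,
                     seed = derive_seed(seed, paste0("tracks/", nm)))
    write_table(tr, file.path(config$out_dir, paste0("tracks_", nm, ".csv")))
    summary$track_speed_um_s[[nm]] <-
      mean(vapply(tr, track_speed, numeric(1)))
  }

  # --- ageing ---
  summary$median_lifespan <- list()
  for (nm in st$ageing$presets) {
    coh <- simulate_cohort(preset("ageing", nm), st$ageing$n_mothers,
                           seed = derive_seed(seed, paste0("ageing/", nm)))
    ss <- survival_summary(coh)
    utils::write.csv(ss$curve,
                     file.path(config$out_dir, paste0("survival_", nm, ".csv")),
                     row.names = FALSE)
    summary$median_lifespan[[nm]] <- ss$median
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Write the canonical small synthetic fixture set
#'
#' One small dataset per generator, regenerated identically from the
#' pinned seed, plus a manifest with MD5 checksums.
#'
#' @param dir Output directory (created if needed).
#' @param seed Pinned seed.
#' @return Path of the manifest file, invisibly.
#' @export
make_fixtures <- function(dir, seed = 20140101L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(gen_segregation_counts(preset("segregation", "wt"), 2000,
                                     seed = derive_seed(seed, "counts")),
              file.path(dir, "counts_wt.csv"))
  fl <- gen_flip_series(preset("flip", "circle_adjacent"),
                        seed = derive_seed(seed, "flip"))
  write_table(fl, file.path(dir, "traces_flip.csv"))
  write_table(gen_division_records(preset("division", "wt_loaded"), 50,
                                   seed = derive_seed(seed, "div")),
              file.path(dir, "divisions_wt_loaded.csv"))
  write_table(gen_tracks(preset("tracks", "wt"), 10,
                         seed = derive_seed(seed, "tracks")),
              file.path(dir, "tracks_wt.csv"))
  write_table(gen_pedigree_table(preset("pedigree", "wt"), 500,
                                 seed = derive_seed(seed, "pedigree")),
              file.path(dir, "pedigree_wt.csv"))
  write_table(gen_sector_colonies(preset("sectors", "wt"), 2000,
                                  seed = derive_seed(seed, "colonies")),
              file.path(dir, "colonies_wt.csv"))
  write_nucleus_image(gen_nucleus_image(preset("nucleus", "wt_loaded"),
                                        loaded = TRUE,
                                        seed = derive_seed(seed, "nucleus")),
                      file.path(dir, "nucleus_wt_loaded.tiff"))
  files <- sort(setdiff(list.files(dir), "manifest.csv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
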