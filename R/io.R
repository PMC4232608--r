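#' Read a typed measurement table
#'
#' CSV readers for the pipeline's documented schemas.  Column names and
#' types are validated; violations are hard errors with row context.
#' Schemas: `counts` (`category` in {1,2,4}, `n`, `pct_all_retained`),
#' `traces` (`t_s`, `intensity`, `roi`, `cell_id`), `divisions`
#' (`mother_total`, `bud_total`, `mother_area`, `bud_area`, `age`),
#' `tracks` (`track_id`, `t_s`, `x_um`, `y_um`, `z_um`), `lifespans`
#' (`lifespan`, `died`), `pedigree` (`mother_id`,
#' `mother_circle_count`, `daughter_has_marker`), `colonies`
#' (`colony_id`, `sector_class`).
#'
#' @param path CSV file path (comma-separated, UTF-8, "." decimal,
#'   header row mandatory).
#' @param schema_id One of the schema names above.
#' @return The matching typed object: `segregation_counts`, list of
#'   `fluor_trace`, `division_records`, list of `track`, numeric
#'   lifespans, `pedigree_table` or `colony_table`.
#' @export
read_table <- function(path, schema_id = c("counts", "traces", "divisions",
                                           "tracks", "lifespans",
                                           "pedigree", "colonies")) {
  schema_id <- match.arg(schema_id)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- switch(schema_id,
    counts = c("category", "n", "pct_all_retained"),
    traces = c("t_s", "intensity", "roi", "cell_id"),
    divisions = c("mother_total", "bud_total", "mother_area", "bud_area", "age"),
    tracks = c("track_id", "t_s", "x_um", "y_um", "z_um"),
    lifespans = c("lifespan", "died"),
    pedigree = c("mother_id", "mother_circle_count", "daughter_has_marker"),
    colonies = c("colony_id", "sector_class"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    abort_input(sprintf("%s: schema '%s' requires missing column(s): %s",
                        path, schema_id, paste(missing_cols, collapse = ", ")))
  unknown <- setdiff(names(df), need)
  if (length(unknown))
    abort_input(sprintf("%s: unknown column(s) for schema '%s': %s",
                        path, schema_id, paste(unknown, collapse = ", ")))
  switch(schema_id,
    counts = parse_counts(df, path),
    traces = parse_traces(df, path),
    divisions = {
      class(df) <- c("division_records", class(df))
      df
    },
    tracks = parse_tracks(df, path),
    lifespans = df$lifespan,
    pedigree = {
      df$daughter_has_marker <- as.logical(df$daughter_has_marker)
      class(df) <- c("pedigree_table", class(df))
      df
    },
    colonies = {
      df$sector_class <- factor(df$sector_class,
                                levels = c("half", "other", "none"))
      if (anyNA(df$sector_class))
        abort_input(sprintf("%s: sector_class must be half/other/none", path))
      class(df) <- c("colony_table", class(df))
      df
    })
}

parse_counts <- function(df, path) {
  if (!setequal(df$category, c(1, 2, 4)) || nrow(df) != 3)
    abort_input(sprintf("%s: counts table needs exactly the categories 1, 2, 4",
                        path))
  df <- df[order(df$category), ]
  new_segregation_counts(x = df$n[1], y = df$n[2], z = df$n[3],
                         a = df$pct_all_retained[1],
                         b = df$pct_all_retained[2],
                         c = df$pct_all_retained[3])
}

parse_traces <- function(df, path) {
  out <- lapply(split(df, df$cell_id), function(d) {
    if (any(diff(d$t_s) <= 0))
      abort_input(sprintf("%s: non-monotone time base for cell_id '%s'",
                          path, d$cell_id[1]))
    new_fluor_trace(d$t_s, d$intensity, roi = d$roi[1])
  })
  out
}

parse_tracks <- function(df, path) {
  lapply(split(df, df$track_id), function(d) {
    if (any(diff(d$t_s) <= 0))
      abort_input(sprintf("%s: non-monotone time base for track_id '%s'",
                          path, d$track_id[1]))
    structure(list(t = d$t_s,
                   xyz = cbind(d$x_um, d$y_um, d$z_um)),
              class = "track")
  })
}

#' Write pipeline objects as schema CSVs
#'
#' Inverse of [read_table()] for the generator outputs; round-trips are
#' exact to CSV precision (15 significant digits).
#'
#' @param x A `segregation_counts`, list of `fluor_trace`, list of
#'   `track`, `division_records`, `pedigree_table` or `colony_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  df <- if (inherits(x, "segregation_counts")) {
    data.frame(category = c(1L, 2L, 4L), n = c(x$x, x$y, x$z),
               pct_all_retained = c(x$a, x$b, x$c))
  } else if (is.list(x) && length(x) && inherits(x[[1]], "fluor_trace")) {
    ids <- names(x) %||% seq_along(x)
    do.call(rbind, lapply(seq_along(x), function(i)
      data.frame(t_s = x[[i]]$t, intensity = x[[i]]$I, roi = x[[i]]$roi,
                 cell_id = ids[i])))
  } else if (is.list(x) && length(x) && inherits(x[[1]], "track")) {
    do.call(rbind, lapply(seq_along(x), function(i)
      data.frame(track_id = i, t_s = x[[i]]$t,
                 x_um = x[[i]]$xyz[, 1], y_um = x[[i]]$xyz[, 2],
                 z_um = x[[i]]$xyz[, 3])))
  } else if (inherits(x, "division_records")) {
    x[c("mother_total", "bud_total", "mother_area", "bud_area", "age")]
  } else if (inherits(x, "pedigree_table") || inherits(x, "colony_table")) {
    as.data.frame(x)
  } else {
    abort_input("unsupported object for write_table")
  }
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a nucleus image as TIFF plus truth sidecar
#'
#' The green channel goes to a single-plane 16-bit TIFF; the ground
#' truth (and the intensity scale needed to restore absolute counts)
#' goes to a JSON sidecar next to it.
#'
#' @param image A `nucleus_image`.
#' @param path Output `.tiff` path; the sidecar is `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_nucleus_image <- function(image, path) {
  stopifnot(inherits(image, "nucleus_image"))
  scale <- max(image$pixels)
  tiff::writeTIFF(image$pixels / scale, path, bits.per.sample = 16)
  side <- c(image$truth, list(pixel_size = image$pixel_size,
                              intensity_scale = scale))
  jsonlite::write_json(side, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nucleus_image
#' @export
read_nucleus_image <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".truth.json"),
                              simplifyVector = TRUE)
  px <- tiff::readTIFF(path) * side$intensity_scale
  structure(list(pixels = px, red = NULL, pixel_size = side$pixel_size,
                 truth = side[setdiff(names(side),
                                      c("pixel_size", "intensity_scale"))]),
            class = "nucleus_image")
}
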