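#' Region-of-interest helpers for nucleus images
#'
#' `roi_disk()` returns a logical pixel mask covering the nucleus (rim
#' annulus plus interior); `roi_background()` masks pixels beyond the
#' rim where the generator places no signal.  Pixels are 0-based with
#' centres at integer positions; masks are half-open pixel sets.
#'
#' @param image A `nucleus_image`.
#' @param radius_um Disk radius; defaults to the truth rim radius plus
#'   the truncated blur extent.
#' @param margin_px Extra margin (pixels) between the disk and the
#'   background region.
#' @return Logical matrix of the image's dimensions.
#' @export
roi_disk <- function(image, radius_um = NULL) {
  geo <- image_geometry(image)
  if (is.null(radius_um))
    radius_um <- image$truth$radius_um +
      image$truth$trunc_sd * image$truth$psf_sd_um
  geo$r <= radius_um
}

#' @rdname roi_disk
#' @export
roi_background <- function(image, margin_px = 2) {
  geo <- image_geometry(image)
  rim_out <- image$truth$radius_um +
    image$truth$trunc_sd * image$truth$psf_sd_um
  geo$r > rim_out + margin_px * image$pixel_size
}

image_geometry <- function(image) {
  pixel_geometry(nrow(image$pixels), image$pixel_size)
}

#' Background-subtracted integrated fluorescence
#'
#' Sum of intensities over the ROI minus the background region's mean
#' times the ROI area, as measured on sum projections.  Negative results
#' are reported as-is, never clipped.
#'
#' @param image A `nucleus_image`.
#' @param roi Logical pixel mask (default: nucleus disk).
#' @param bg Logical pixel mask for background estimation (default: the
#'   signal-free outskirts).
#' @return Integrated fluorescence (A.U.).
#' @export
integrated_fluorescence <- function(image, roi = NULL, bg = NULL) {
  stopifnot(inherits(image, "nucleus_image"))
  if (is.null(roi)) roi <- roi_disk(image)
  if (is.null(bg)) bg <- roi_background(image)
  if (!any(bg)) abort_input("background region is empty")
  sum(image$pixels[roi]) - mean(image$pixels[bg]) * sum(roi)
}

#' NPC cap intensity quantification (Ic / Ir / Io)
#'
#' Measures the mean background-subtracted rim intensity adjacent to the
#' accumulated circles (`Ic`), in the residual rim (`Ir`) and in the
#' equidistant area opposite the circles (`Io`), then normalizes all
#' values by the cohort median of `Ir` (so the cohort `Ir` median is 1
#' by construction).
#'
#' @param images A `nucleus_image` or list of them (the cohort).
#' @param circle_angle Angular position(s) of the circle cluster
#'   (radians); defaults to each image's ground truth.
#' @param cap_span Angular width of the `Ic` sector; defaults to truth.
#' @param band_sd Half-width of the rim band in units of the blur SD.
#' @return A `cap_quant` data frame with columns `Ic`, `Ir`, `Io` (one
#'   row per cell) and attribute `ir_median_raw`, the raw normalizer.
#' @examples
#' imgs <- gen_nucleus_cohort(preset("nucleus", "wt_loaded"), 5)
#' mean(cap_ratio(imgs)$Ic)
#' @export
cap_ratio <- function(images, circle_angle = NULL, cap_span = NULL,
                      band_sd = 1.5) {
  if (inherits(images, "nucleus_image")) images <- list(images)
  raw <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    stopifnot(inherits(img, "nucleus_image"))
    ang <- circle_angle[i] %||% img$truth$plasmid_angle
    span <- cap_span %||% img$truth$cap_span
    if (!is.finite(ang))
      abort_input("circle_angle needed for images without a loaded truth")
    geo <- image_geometry(img)
    band <- abs(geo$r - img$truth$radius_um) <=
      band_sd * img$truth$psf_sd_um
    if (!any(band)) abort_input("rim band is empty")
    dcap <- angular_distance(geo$theta, ang)
    in_cap <- band & dcap <= span / 2
    opp <- band & angular_distance(geo$theta, ang + pi) <= span / 2
    if (!any(in_cap)) abort_input("circle region does not intersect the rim")
    bgval <- mean(img$pixels[roi_background(img)])
    c(Ic = mean(img$pixels[in_cap]) - bgval,
      Ir = mean(img$pixels[band & !in_cap]) - bgval,
      Io = mean(img$pixels[opp]) - bgval)
  })
  raw <- do.call(rbind, raw)
  med <- stats::median(raw[, "Ir"])
  if (med <= 0) abort_input("cohort median rim intensity is not positive")
  out <- as.data.frame(raw / med)
  attr(out, "ir_median_raw") <- med
  class(out) <- c("cap_quant", class(out))
  out
}

#' Percentage of fluorescence segregated to the mother
#'
#' `100 * mother_total / (mother_total + bud_total)`; the mother and bud
#' percentages of a division sum to 100 exactly.
#'
#' @param record A `division_records` data frame (or any data frame with
#'   `mother_total` and `bud_total`), or a single numeric mother total.
#' @param bud_total Bud total when `record` is numeric.
#' @return Percentage(s) in `[0, 100]`.
#' @export
percent_to_mother <- function(record, bud_total = NULL) {
  if (is.numeric(record)) {
    mt <- record
    bt <- bud_total
  } else {
    mt <- record$mother_total
    bt <- record$bud_total
  }
  if (is.null(bt)) abort_input("bud totals are required")
  if (any(mt < 0 | bt < 0)) abort_input("totals must be non-negative")
  tot <- mt + bt
  if (any(tot <= 0)) abort_input("total fluorescence must be positive")
  100 * mt / tot
}

#' Extract an intensity trace along the nuclear rim
#'
#' Bilinear sampling of the image along the circle of given centre and
#' radius, with an arc step of at most half a pixel.  Channel
#' normalizations follow the assay: green by its mean, red (when the
#' image carries a plasmid channel) by its maximum.
#'
#' @param image A `nucleus_image`.
#' @param center Centre in pixel coordinates (defaults to truth).
#' @param radius Radius in um (defaults to the truth rim radius).
#' @return A [new_rim_profile()].
#' @export
extract_rim_trace <- function(image, center = NULL, radius = NULL) {
  stopifnot(inherits(image, "nucleus_image"))
  center <- center %||% image$truth$center_px
  radius <- radius %||% image$truth$radius_um
  step <- image$pixel_size / 2
  L <- ceiling(2 * pi * radius / step)
  theta <- (seq_len(L) - 1L) * 2 * pi / L
  xs <- center[1] + (radius / image$pixel_size) * cos(theta)
  ys <- center[2] + (radius / image$pixel_size) * sin(theta)
  bgval <- mean(image$pixels[roi_background(image)])
  green <- pmax(bilinear_sample(image$pixels, xs, ys) - bgval, 0)
  red <- if (!is.null(image$red)) {
    pmax(bilinear_sample(image$red, xs, ys) -
           mean(image$red[roi_background(image)]), 0)
  } else green
  new_rim_profile(s = theta * radius, green = green, red = red,
                  truth = list(theta = theta, radius_um = radius))
}

# bilinear interpolation at fractional pixel positions (x = column
# index, y = row index, both 0-based at pixel centres)
bilinear_sample <- function(mat, x, y) {
  n <- nrow(mat); m <- ncol(mat)
  x0 <- pmax(pmin(floor(x), m - 2), 0)
  y0 <- pmax(pmin(floor(y), n - 2), 0)
  fx <- pmin(pmax(x - x0, 0), 1)
  fy <- pmin(pmax(y - y0, 0), 1)
  idx <- function(r, c) mat[cbind(r + 1L, c + 1L)]
  (1 - fx) * (1 - fy) * idx(y0, x0) +
    fx * (1 - fy) * idx(y0, x0 + 1L) +
    (1 - fx) * fy * idx(y0 + 1L, x0) +
    fx * fy * idx(y0 + 1L, x0 + 1L)
}

#' Align rim profiles on the plasmid peak and average them
#'
#' Circularly shifts each profile so its red-channel peak maps to the
#' origin, averages the green channels, and reports the enrichment of
#' the NPC signal inside the co-localization window around the plasmid:
#' `100 * (mean inside +/- window / baseline - 1)` percent, with the
#' baseline taken outside the window (default) or over the whole trace.
#'
#' @param profiles List of >= 1 [new_rim_profile()]s on a common grid
#'   (>= 2 for a cohort average; a single profile is allowed for
#'   noiseless checks).
#' @param window_um Half-width of the window around the aligned peak
#'   (um); default 0.130 (130 nm).
#' @param baseline `"outside"` or `"whole"`.
#' @return List with `s` (arc offsets), `green_mean`, `red_mean`,
#'   `enrichment_pct` and `n`.
#' @export
align_and_average_profiles <- function(profiles, window_um = 0.130,
                                       baseline = c("outside", "whole")) {
  baseline <- match.arg(baseline)
  if (inherits(profiles, "rim_profile")) profiles <- list(profiles)
  if (!length(profiles)) abort_input("need at least one profile")
  L <- length(profiles[[1]]$s)
  step <- profiles[[1]]$s[2] - profiles[[1]]$s[1]
  shift_to_origin <- function(v, peak) {
    if (peak == 1L) v else c(v[peak:L], v[seq_len(peak - 1L)])
  }
  greens <- vapply(profiles, function(p) {
    if (length(p$s) != L) abort_input("profiles must share one arc grid")
    shift_to_origin(p$green, p$peak_index)
  }, numeric(L))
  reds <- vapply(profiles, function(p) shift_to_origin(p$red, p$peak_index),
                 numeric(L))
  gmean <- rowMeans(greens)
  rmean <- rowMeans(reds)
  offs <- (seq_len(L) - 1L) * step
  d <- pmin(offs, L * step - offs)  # circular distance to the aligned peak
  inside <- d <= window_um + 1e-12
  base <- if (baseline == "outside") mean(gmean[!inside]) else mean(gmean)
  list(s = offs, green_mean = gmean, red_mean = rmean,
       enrichment_pct = 100 * (mean(gmean[inside]) / base - 1),
       n = length(profiles))
}

#' Classify plasmid foci as rim-associated or resolvably interior
#'
#' A focus is `resolvable` iff its radial distance from the rim circle
#' exceeds the resolution threshold:
#' `| ||pos - center|| - radius | > threshold_um`.
#'
#' @param plasmid_pos Matrix of focus positions (rows; um) or a single
#'   position vector.
#' @param center Nucleus centre (um, same dimensionality).
#' @param radius Rim radius (um).
#' @param threshold_um Resolution threshold; default 0.25 um.
#' @return Factor with levels `at_rim`, `resolvable`.
#' @export
classify_rim_proximity <- function(plasmid_pos, center, radius,
                                   threshold_um = 0.25) {
  if (is.null(dim(plasmid_pos))) plasmid_pos <- matrix(plasmid_pos, nrow = 1)
  d <- sqrt(rowSums(sweep(plasmid_pos, 2, center)^2))
  factor(ifelse(abs(d - radius) > threshold_um, "resolvable", "at_rim"),
         levels = c("at_rim", "resolvable"))
}

#' Mean 3-D speed of a particle track
#'
#' Mean over intervals of the 3-D step length divided by the frame
#' interval (distance covered per time point, divided by the 3 s frame
#' time in the assay's acquisition).
#'
#' @param track A `track` (list with `t` and `xyz`).
#' @return Speed in um/s.
#' @export
track_speed <- function(track) {
  stopifnot(!is.null(track$t), !is.null(track$xyz))
  dt <- diff(track$t)
  if (any(abs(dt - dt[1]) > 1e-9)) abort_input("track time base must be uniform")
  steps <- sqrt(rowSums(diff(track$xyz)^2))
  mean(steps / dt)
}

#' Fit an age trend to per-cell measurements
#'
#' Sorts measurements by mother age, groups 10 consecutive values into
#' summary dots (mean age, mean value, SD), and fits either a one-phase
#' association curve `V(age) = V0 + (plateau - V0) * (1 - exp(-r age))`
#' (NPC asymmetry versus age) or an exponential `V(age) = a *
#' exp(lambda age)` whose values are then renormalized by the fitted
#' intercept (G1 pore totals versus age).
#'
#' @param age,value Paired measurements (>= 20 points spanning >= 10
#'   generations).
#' @param model `"one_phase_association"` or `"exponential"`.
#' @param group_size Points per summary dot (default 10).
#' @return An `age_trend`: list with `raw`, `dots`, `fit` (model,
#'   params, converged) and, for the exponential model, `normalized`
#'   values (fitted intercept set to 1).
#' @export
age_trend <- function(age, value,
                      model = c("one_phase_association", "exponential"),
                      group_size = 10) {
  model <- match.arg(model)
  if (length(age) != length(value)) abort_input("age and value lengths differ")
  if (length(age) < 20) abort_input("need at least 20 points")
  if (diff(range(age)) < 10) abort_input("ages must span at least 10 generations")
  ord <- order(age)
  age <- age[ord]; value <- value[ord]
  grp <- (seq_along(age) - 1L) %/% group_size
  dots <- data.frame(
    age = tapply(age, grp, mean),
    value = tapply(value, grp, mean),
    sd = tapply(value, grp, stats::sd))

  if (stats::var(value) < 1e-12) {
    fit <- list(model = model, params = c(V0 = value[1], plateau = value[1],
                                          rate = 0),
                converged = TRUE, degenerate = TRUE)
    return(structure(list(raw = data.frame(age = age, value = value),
                          dots = dots, fit = fit, normalized = NULL),
                     class = "age_trend"))
  }

  if (model == "one_phase_association") {
    v0 <- mean(value[seq_len(min(group_size, length(value)))])
    vinf <- mean(utils::tail(value, group_size))
    nls_fit <- lm_curve_fit(
      par = c(V0 = v0, plateau = vinf, r = 2 / max(age)),
      lower = c(V0 = -Inf, plateau = -Inf, r = 1e-10),
      resid_fn = function(p) value - (p[["V0"]] +
        (p[["plateau"]] - p[["V0"]]) * (1 - exp(-p[["r"]] * age))))
    if (is.null(nls_fit)) abort_input("one-phase association fit did not converge")
    cf <- nls_fit$par
    fit <- list(model = model,
                params = c(V0 = cf[["V0"]], plateau = cf[["plateau"]],
                           rate = cf[["r"]]),
                converged = TRUE, degenerate = FALSE)
    normalized <- NULL
  } else {
    if (any(value <= 0)) abort_input("exponential model requires positive values")
    init <- stats::coef(stats::lm(log(value) ~ age))
    nls_fit <- lm_curve_fit(
      par = c(a = exp(unname(init[1])), lambda = unname(init[2])),
      lower = c(a = 1e-12, lambda = -Inf),
      resid_fn = function(p) value - p[["a"]] * exp(p[["lambda"]] * age))
    if (is.null(nls_fit)) abort_input("exponential fit did not converge")
    cf <- nls_fit$par
    fit <- list(model = model,
                params = c(intercept = cf[["a"]], lambda = cf[["lambda"]]),
                converged = TRUE, degenerate = FALSE)
    normalized <- value / cf[["a"]]
  }
  structure(list(raw = data.frame(age = age, value = value), dots = dots,
                 fit = fit, normalized = normalized),
            class = "age_trend")
}

#' @export
print.age_trend <- function(x, ...) {
  cat("<age_trend>", x$fit$model, "\n")
  print(signif(x$fit$params, 5))
  invisible(x)
}
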