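test_that("nucleus generator rejects impossible geometry", {
  expect_error(gen_nucleus_image(modify_preset(preset("nucleus", "wt_loaded"),
                                               cap_span = 0)),
               "cap_span")
  expect_error(gen_nucleus_image(modify_preset(preset("nucleus", "wt_loaded"),
                                               cap_span = 7)),
               "cap_span")
  expect_error(gen_nucleus_image(modify_preset(preset("nucleus", "wt_loaded"),
                                               radius_um = 3)),
               "half the image extent")
  expect_error(gen_nucleus_image(modify_preset(preset("nucleus", "wt_loaded"),
                                               cap_ratio = 0.5)),
               "cap_ratio")
})

test_that("integrated fluorescence reproduces the generator's photon
           bookkeeping on noiseless images", {
  img <- gen_nucleus_image(det_nucleus_preset(), loaded = TRUE, seed = 9,
                           noiseless = TRUE)
  f <- integrated_fluorescence(img)
  expect_equal(f, img$truth$total_signal, tolerance = 1e-9)
  # uniform image at background level integrates to zero
  uni <- img
  uni$pixels <- matrix(10, nrow(img$pixels), ncol(img$pixels))
  expect_equal(integrated_fluorescence(uni), 0, tolerance = 1e-9)
})

test_that("cap quantification recovers the generating ratio and normalizes
           the residual rim to 1", {
  pr <- det_nucleus_preset(cap_ratio = 3)
  img <- gen_nucleus_image(pr, loaded = TRUE, seed = 9, noiseless = TRUE)
  cq <- cap_ratio(list(img))
  expect_equal(cq$Ic / cq$Ir, 3, tolerance = 0.01)
  # uniform rim: Ic = Ir = 1
  img0 <- gen_nucleus_image(det_nucleus_preset("unloaded"), loaded = FALSE,
                            seed = 9, noiseless = TRUE)
  cq0 <- cap_ratio(list(img0), circle_angle = 1.0, cap_span = pi / 2)
  expect_equal(cq0$Ic, 1, tolerance = 0.02)
  expect_equal(cq0$Ir, 1, tolerance = 0.02)
  # invariant to global intensity rescaling
  img2 <- img
  img2$pixels <- img$pixels * 7
  expect_equal(cap_ratio(list(img2))$Ic, cq$Ic, tolerance = 1e-9)
  # cohort Ir median is 1 by construction
  cohort <- gen_nucleus_cohort(preset("nucleus", "wt_loaded"), 15, seed = 13)
  expect_equal(stats::median(cap_ratio(cohort)$Ir), 1, tolerance = 1e-12)
})

test_that("mother and bud percentages are exact complements", {
  rec <- gen_division_records(preset("division", "wt_loaded"), 30, seed = 5)
  pm <- percent_to_mother(rec)
  pb <- percent_to_mother(rec$bud_total, rec$mother_total)
  expect_equal(pm + pb, rep(100, 30), tolerance = 1e-12)
  expect_equal(percent_to_mother(5, 5), 50)
  expect_error(percent_to_mother(-1, 5), "non-negative")
})

test_that("division cohorts hit the preset retention medians", {
  loaded <- gen_division_records(preset("division", "wt_loaded"), 50, seed = 7)
  expect_lt(abs(stats::median(percent_to_mother(loaded)) - 78), 3)
  unl <- gen_division_records(preset("division", "unloaded"), 50, seed = 8)
  expect_lt(abs(stats::median(percent_to_mother(unl)) - 63), 3)
})

test_that("rim traces read the angular cap profile off the image", {
  pr <- det_nucleus_preset(cap_ratio = 3)
  img <- gen_nucleus_image(pr, loaded = TRUE, seed = 9, noiseless = TRUE)
  tr <- extract_rim_trace(img)
  expect_equal(max(tr$green) / min(tr$green), 3, tolerance = 0.05 / 3)
  expect_equal(mean(tr$green), 1, tolerance = 1e-9)
  # red-channel peak sits at the plasmid angle to within one sample
  step <- tr$truth$theta[2] - tr$truth$theta[1]
  dpeak <- abs(tr$truth$theta[tr$peak_index] - img$truth$plasmid_angle)
  expect_lt(min(dpeak, 2 * pi - dpeak), 1.5 * step)
  # uniform rim gives a flat unit trace
  img0 <- gen_nucleus_image(det_nucleus_preset("unloaded"), loaded = FALSE,
                            seed = 9, noiseless = TRUE)
  tr0 <- extract_rim_trace(img0)
  expect_lt(max(abs(tr0$green - 1)), 0.02)
})

test_that("rim-proximity classification applies the resolution threshold
           and is monotone in it", {
  expect_identical(as.character(classify_rim_proximity(c(1, 0), c(0, 0), 1)),
                   "at_rim")
  expect_identical(as.character(classify_rim_proximity(c(0, 0), c(0, 0), 1,
                                                       threshold_um = 0.25)),
                   "resolvable")
  # cohort with 15% interior placement classifies ~15% resolvable
  set.seed(77)
  n <- 2000
  interior <- stats::runif(n) < 0.15
  r <- ifelse(interior, stats::runif(n, 0, 0.5), 1)
  ang <- stats::runif(n, 0, 2 * pi)
  pos <- cbind(r * cos(ang), r * sin(ang))
  cls <- classify_rim_proximity(pos, c(0, 0), 1, threshold_um = 0.25)
  expect_lt(abs(100 * mean(cls == "resolvable") - 15), 3)
  fracs <- vapply(c(0.1, 0.25, 0.4), function(th)
    mean(classify_rim_proximity(pos, c(0, 0), 1, th) == "resolvable"),
    numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("track speeds follow the chi(3) step-length law", {
  pr <- preset("tracks", "wt")
  # static track
  still <- list(t = (0:10) * 3, xyz = matrix(0, 11, 3))
  expect_identical(track_speed(still), 0)
  # unconfined sigma = 0.1: mean step length = chi(3) mean = 0.15958 um
  pr2 <- modify_preset(pr, step_sd_um = 0.1, confine_um = 0, n_points = 201)
  tr <- gen_tracks(pr2, 50, seed = 81)
  steps <- unlist(lapply(tr, function(t) sqrt(rowSums(diff(t$xyz)^2))))
  chi3_mean <- 0.1 * sqrt(2) * gamma(2) / gamma(3 / 2)
  expect_equal(mean(steps), chi3_mean, tolerance = 0.002 / chi3_mean)
  # uniform time base is enforced
  bad <- list(t = c(0, 3, 7), xyz = matrix(0, 3, 3))
  expect_error(track_speed(bad), "uniform")
})

test_that("age trends group by tens and recover generating parameters", {
  # constant values: association plateau at the constant, rate ~ 0
  at0 <- age_trend(seq(0, 35, length.out = 60), rep(70, 60))
  expect_true(at0$fit$degenerate)
  expect_equal(unname(at0$fit$params[["plateau"]]), 70)
  expect_equal(unname(at0$fit$params[["rate"]]), 0)
  # association round trip: 56 -> 78 with rate 0.12
  set.seed(91)
  age <- stats::runif(300, 0, 35)
  val <- 56 + (78 - 56) * (1 - exp(-0.12 * age)) + stats::rnorm(300, 0, 3)
  at <- age_trend(age, val)
  expect_true(at$fit$params[["plateau"]] >= 74 && at$fit$params[["plateau"]] <= 82)
  expect_equal(nrow(at$dots), 30)
  expect_equal(unname(at$dots$age[1]), mean(sort(age)[1:10]))
  # exponential growth: lambda within 10%, values renormalized to intercept 1
  g1 <- 100 * exp(0.045 * age) * exp(stats::rnorm(300, 0, 0.1))
  at2 <- age_trend(age, g1, model = "exponential")
  expect_equal(at2$fit$params[["lambda"]], 0.045, tolerance = 0.1)
  expect_equal(length(at2$normalized), 300)
  expect_error(age_trend(1:19, 1:19), "at least 20")
  expect_error(age_trend(rep(1:5, 5), rnorm(25)), "span")
})
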