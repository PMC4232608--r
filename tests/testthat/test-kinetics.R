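flip_grid <- function() (0:29) * 9

test_that("acquisition-loss correction subtracts the neighbor loss exactly", {
  tt <- flip_grid()
  # flat neighbors: output equals the (normalized) input
  target <- new_fluor_trace(tt, 100 * exp(-0.01 * tt))
  flat_nb <- replicate(5, new_fluor_trace(tt, rep(80, 30)), simplify = FALSE)
  corr <- correct_acquisition_loss(target, flat_nb)
  expect_equal(corr$I, 100 * exp(-0.01 * tt) / exp(0) , tolerance = 1e-12)
  expect_true(corr$normalized)
  # target declining purely by imaging loss corrects to a flat 100% line
  loss <- 1 * (seq_along(tt) - 1)
  declining <- new_fluor_trace(tt, 100 - loss)
  nbs <- replicate(5, new_fluor_trace(tt, 90 - loss), simplify = FALSE)
  flat <- correct_acquisition_loss(declining, nbs)
  expect_equal(flat$I, rep(100, 30), tolerance = 1e-12)
  # mismatched time bases are rejected
  expect_error(
    correct_acquisition_loss(target, list(new_fluor_trace(tt + 1, rep(80, 30)))),
    "time base")
})

test_that("decay rate survives an imaging-loss round trip after correction", {
  pr <- modify_preset(preset("flip", "circle_adjacent"),
                      k_decay = 0.01, acq_loss_per_frame = 0.2)
  fl <- gen_flip_series(pr, noiseless = TRUE)
  nbs <- replicate(5, new_fluor_trace(flip_grid(),
                                      100 - 0.2 * (0:29)), simplify = FALSE)
  fit <- fit_exponential_decay(correct_acquisition_loss(fl$a, nbs))
  expect_equal(fit$params[["k"]], 0.01, tolerance = 0.02)
})

test_that("noiseless decay fits recover rate and plateau essentially exactly", {
  pr <- modify_preset(preset("flip", "circle_adjacent"), k_decay = 0.02)
  fit <- fit_exponential_decay(gen_flip_series(pr, noiseless = TRUE)$a)
  expect_equal(fit$params[["k"]], 0.02, tolerance = 1e-6)
  expect_equal(fit$params[["plateau"]], 0, tolerance = 1e-4)
  expect_true(fit$converged)
  pr2 <- modify_preset(preset("flip", "circle_adjacent"), immobile_frac = 0.4)
  fit2 <- fit_exponential_decay(gen_flip_series(pr2, noiseless = TRUE)$a)
  expect_equal(fit2$params[["plateau"]], 40, tolerance = 0.01 / 40)
})

test_that("time-to-fraction matches the mono-exponential closed form", {
  pr <- modify_preset(preset("flip", "circle_adjacent"), k_decay = 0.0142669949)
  fit <- fit_exponential_decay(gen_flip_series(pr, noiseless = TRUE)$a)
  for (q in c(0.7, 0.5, 0.4))
    expect_lt(abs(time_to_fraction(fit, q) - log(1 / q) / 0.0142669949), 1e-6)
  expect_identical(time_to_fraction(fit, 1), 0)
  # levels below the plateau are unreachable
  pr2 <- modify_preset(preset("flip", "circle_adjacent"), immobile_frac = 0.8)
  fit2 <- fit_exponential_decay(gen_flip_series(pr2, noiseless = TRUE)$a)
  expect_identical(time_to_fraction(fit2, 0.7), Inf)
})

test_that("a fully immobile pool gives a flat trace with unreachable t70", {
  pr <- modify_preset(preset("flip", "circle_adjacent"), immobile_frac = 1)
  fit <- fit_exponential_decay(gen_flip_series(pr, noiseless = TRUE)$a)
  expect_identical(fit$t_q[["0.7"]], Inf)
})

test_that("noisy decay fits track the generating rate (median over 100 pairs)", {
  set.seed(55)
  tt <- flip_grid()
  rel <- vapply(1:100, function(i) {
    k <- stats::runif(1, 0.004, 0.03)
    plat <- stats::runif(1, 0, 40)
    I <- pmax(plat + (100 - plat) * exp(-k * tt) + stats::rnorm(30, 0, 2), 0)
    fit <- fit_exponential_decay(new_fluor_trace(tt, I, normalized = TRUE))
    abs(fit$params[["k"]] - k) / k
  }, numeric(1))
  expect_lt(stats::median(rel), 0.05)
})

test_that("barrier index is 1 for identical kinetics and the k-ratio for
           mono-exponential pairs", {
  fl <- gen_flip_series(preset("flip", "barrier_wt"), noiseless = TRUE)
  expect_lt(abs(barrier_index(fl$a, fl$a)$value - 1), 1e-9)
  pr <- modify_preset(preset("flip", "barrier_wt"),
                      k_mother = 0.02, k_bud = 0.01)
  fl2 <- gen_flip_series(pr, noiseless = TRUE)
  bi <- barrier_index(fl2$a, fl2$b)
  expect_equal(bi$value, 2, tolerance = 1e-6)
  expect_equal(bi$q_lost, 0.40)
  # invariant to common rescaling of both traces
  scale_trace <- function(tr, s) new_fluor_trace(tr$t, tr$I * s, tr$roi)
  bi_s <- barrier_index(scale_trace(fl2$a, 3), scale_trace(fl2$b, 3))
  expect_equal(bi_s$value, bi$value, tolerance = 1e-6)
})

test_that("the wild-type barrier outranks the barrier-less mutant across seeds", {
  wins <- vapply(1:100, function(i) {
    wt <- gen_flip_series(preset("flip", "barrier_wt"),
                          seed = derive_seed(61, paste0("wt", i)))
    mt <- gen_flip_series(preset("flip", "barrier_bud6"),
                          seed = derive_seed(61, paste0("mt", i)))
    barrier_index(wt$a, wt$b)$value > barrier_index(mt$a, mt$b)$value
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("FRAP recovery fits solve t15 in closed form and flag shallow
           plateaus", {
  fr <- gen_frap_series(preset("frap", "default"), noiseless = TRUE)
  fit <- fit_recovery(fr)
  expect_equal(fit$t_q[["t15"]], -log(1 - 15 / 100) / 0.0325, tolerance = 1e-4)
  pr <- modify_preset(preset("frap", "default"), plateau = 30)
  fit2 <- fit_recovery(gen_frap_series(pr, noiseless = TRUE))
  expect_equal(fit2$t_q[["t15"]], -log(1 - 15 / 30) / 0.0325, tolerance = 1e-4)
  expect_equal(fit2$t_q[["t15"]], 21.3, tolerance = 0.1 / 21.3)
  pr3 <- modify_preset(preset("frap", "default"), plateau = 10)
  expect_identical(fit_recovery(gen_frap_series(pr3, noiseless = TRUE))$t_q[["t15"]],
                   Inf)
})

test_that("stably anchored pores recover slower than shuttling ones across
           seeds", {
  wins <- vapply(1:60, function(i) {
    st <- fit_recovery(gen_frap_series(preset("frap", "stable_pore"),
                                       seed = derive_seed(71, paste0("s", i))))
    sh <- fit_recovery(gen_frap_series(preset("frap", "shuttling_pore"),
                                       seed = derive_seed(71, paste0("h", i))))
    st$t_q[["t15"]] > sh$t_q[["t15"]]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
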