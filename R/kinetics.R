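#' Correct a photobleaching trace for acquisition loss
#'
#' Imaging itself bleaches fluorescence; the assay corrects for it with
#' unbleached neighboring cells: the mean fluorescence lost by the
#' neighbors at each frame is subtracted from the target trace, which is
#' then normalized — to 100% at the first (last pre-bleach) time point
#' for a FLIP decay, or shifted to 0% at the first post-bleach point for
#' a FRAP recovery.
#'
#' @param trace Target [new_fluor_trace()].
#' @param neighbor_traces List of >= 1 neighbor traces on the same time
#'   base (5 neighbors in the FLIP assay, 3 in the FRAP assay).
#' @param mode `"decay"` (FLIP) or `"recovery"` (FRAP).
#' @return A corrected, normalized `fluor_trace`.
#' @export
correct_acquisition_loss <- function(trace, neighbor_traces,
                                     mode = c("decay", "recovery")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "fluor_trace"))
  if (!length(neighbor_traces)) abort_input("need at least one neighbor trace")
  for (nb in neighbor_traces) {
    if (!inherits(nb, "fluor_trace")) abort_input("neighbors must be fluor_trace")
    if (length(nb$t) != length(trace$t) ||
        max(abs(nb$t - trace$t)) > 1e-9)
      abort_input("neighbor traces must share the target's time base")
  }
  nbI <- rowMeans(vapply(neighbor_traces, function(nb) nb$I,
                         numeric(length(trace$t))))
  corrected <- trace$I - (nbI - nbI[1])
  if (mode == "decay") {
    if (corrected[1] <= 0)
      abort_input("corrected pre-bleach intensity must be positive")
    corrected <- 100 * corrected / corrected[1]
  } else {
    corrected <- corrected - corrected[1]
  }
  new_fluor_trace(trace$t, pmax(corrected, 0), roi = trace$roi,
                  bleach_times = trace$bleach_times, normalized = TRUE)
}

#' Fit a one-phase exponential decay to a FLIP trace
#'
#' Nonlinear least squares on `I(t) = plateau + (I0 - plateau) *
#' exp(-k t)` with `I0` fixed at the first (normalized) intensity — 100
#' for a corrected trace.  The rate is initialized from a log-linear
#' regression on
#' the first half of the trace and the plateau from the final three
#' points.  A perfectly flat trace (fully immobile pool) is returned as
#' a degenerate fit with `k = NA`: every time-to-fraction below the
#' plateau is then flagged unreachable.
#'
#' @param trace A (corrected, normalized) [new_fluor_trace()].
#' @return A `fit_result`: list with `model`, `params` (`k` in s^-1,
#'   `plateau` and `I0` in A.U., `amplitude = I0 - plateau`),
#'   `residual_norm`, `converged`, and `t_q`, the times to decay to 70,
#'   50 and 40% of the initial signal.
#' @examples
#' fl <- gen_flip_series(preset("flip", "opposite"), noiseless = TRUE)
#' fit_exponential_decay(fl$a)$t_q[["0.7"]]  # 25 s
#' @export
fit_exponential_decay <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (length(trace$t) < 5) abort_input("need at least 5 points to fit")
  tt <- trace$t - trace$t[1]
  I <- trace$I

  if (stats::var(I) < 1e-12) {
    fit <- new_fit_result("one_phase_decay",
                          params = c(k = NA_real_, plateau = mean(I),
                                     I0 = mean(I), amplitude = 0),
                          residual_norm = 0, converged = TRUE)
    fit$t_q <- tq_table(fit)
    return(fit)
  }

  plateau0 <- mean(utils::tail(I, 3))
  k0 <- init_rate_loglin(tt, I, plateau0)
  I00 <- I[1]  # fixed by the normalization (100 for corrected traces)
  fit <- lm_curve_fit(
    par = c(k = k0, plateau = min(plateau0, 0.9 * I00)),
    lower = c(k = 1e-10, plateau = 0),
    resid_fn = function(p) I - (p[["plateau"]] +
      (I00 - p[["plateau"]]) * exp(-p[["k"]] * tt)))
  if (is.null(fit)) {
    warning("one-phase decay fit did not converge", call. = FALSE)
    out <- new_fit_result("one_phase_decay",
                          params = c(k = NA_real_, plateau = NA_real_,
                                     I0 = NA_real_, amplitude = NA_real_),
                          residual_norm = NA_real_, converged = FALSE)
    out$t_q <- c("0.7" = NA_real_, "0.5" = NA_real_, "0.4" = NA_real_)
    return(out)
  }
  cf <- fit$par
  out <- new_fit_result("one_phase_decay",
                        params = c(k = cf[["k"]],
                                   plateau = cf[["plateau"]],
                                   I0 = I00,
                                   amplitude = I00 - cf[["plateau"]]),
                        residual_norm = fit$residual_norm,
                        converged = TRUE)
  out$t_q <- tq_table(out)
  out
}

# Levenberg-Marquardt least squares with box constraints; returns NULL
# on failure so callers can flag non-convergence explicitly.
lm_curve_fit <- function(par, lower, resid_fn) {
  res <- tryCatch(
    minpack.lm::nls.lm(par = par, lower = lower, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 1024, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(res) || !res$info %in% 1:4) return(NULL)
  list(par = res$par, residual_norm = sqrt(res$deviance))
}

# log-linear initial rate: regression of log(I - plateau) on t over the
# first half of the trace
init_rate_loglin <- function(tt, I, plateau0) {
  half <- seq_len(max(5L, ceiling(length(tt) / 2)))
  y <- I[half] - min(plateau0, min(I[half]) * 0.5)
  ok <- y > 0
  if (sum(ok) >= 2) {
    sl <- stats::coef(stats::lm(log(y[ok]) ~ tt[half][ok]))[2]
    if (is.finite(sl) && sl < 0) return(unname(-sl))
  }
  1 / max(tt[length(tt)], 1)
}

tq_table <- function(fit, fractions = c(0.7, 0.5, 0.4)) {
  out <- vapply(fractions, function(q) time_to_fraction(fit, q), numeric(1))
  names(out) <- as.character(fractions)
  out
}

new_fit_result <- function(model, params, residual_norm, converged) {
  structure(list(model = model, params = params,
                 residual_norm = residual_norm, converged = converged,
                 t_q = NULL),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model,
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(signif(x$params, 6))
  if (!is.null(x$t_q)) {
    cat("  t_q (s):\n")
    print(signif(x$t_q, 6))
  }
  invisible(x)
}

#' Time for a fitted decay to reach a remaining fraction
#'
#' Solves the fitted one-phase decay for `I = q * I0` (q the remaining
#' fraction of the initial signal): for `plateau = 0` this is the closed
#' form `log(1/q) / k`.  Levels at or below the plateau are unreachable
#' and returned as `Inf` with a warning-free flag (the value itself).
#'
#' @param fit A `fit_result` from [fit_exponential_decay()].
#' @param q_remaining Remaining fraction in (0, 1].
#' @return Seconds (`Inf` if the level is unreachable, 0 for q = 1).
#' @export
time_to_fraction <- function(fit, q_remaining) {
  stopifnot(inherits(fit, "fit_result"), fit$model == "one_phase_decay")
  if (q_remaining <= 0 || q_remaining > 1)
    abort_input("q_remaining must lie in (0, 1]")
  if (q_remaining == 1) return(0)
  p <- fit$params
  if (!is.finite(p[["k"]]) || p[["amplitude"]] <= 0) return(Inf)
  target <- q_remaining * p[["I0"]]
  if (target <= p[["plateau"]]) return(Inf)  # below the immobile plateau
  log(p[["amplitude"]] / (target - p[["plateau"]])) / p[["k"]]
}

#' Barrier index of the bud-neck diffusion barrier
#'
#' Ratio of the times needed to lose a fraction `q_lost` (default 40%)
#' of the initial fluorescence in the bud over the mother compartment
#' during mother-side FLIP.  1 means free exchange; larger values mean a
#' stronger barrier.  Invariant to common rescaling of both traces.
#'
#' @param mother,bud Corrected, normalized [new_fluor_trace()]s.
#' @param q_lost Fraction of signal lost, in (0, 1).
#' @return A `barrier_index`: list with `value`, `q_lost`, `t_mother`,
#'   `t_bud` (seconds).
#' @export
barrier_index <- function(mother, bud, q_lost = 0.40) {
  if (q_lost <= 0 || q_lost >= 1) abort_input("q_lost must lie in (0, 1)")
  fm <- fit_exponential_decay(mother)
  fb <- fit_exponential_decay(bud)
  tm <- time_to_fraction(fm, 1 - q_lost)
  tb <- time_to_fraction(fb, 1 - q_lost)
  structure(list(value = tb / tm, q_lost = q_lost,
                 t_mother = tm, t_bud = tb),
            class = "barrier_index")
}

#' @export
print.barrier_index <- function(x, ...) {
  cat(sprintf("barrier index = %.3f (t_bud %.1f s / t_mother %.1f s, q_lost %.2f)\n",
              x$value, x$t_bud, x$t_mother, x$q_lost))
  invisible(x)
}

#' Fit a one-phase association to a FRAP recovery trace
#'
#' Nonlinear least squares on `I(t) = plateau * (1 - exp(-k t))`.  The
#' time to recover 15 percentage points, `t_15 = -log(1 - 15/plateau)/k`,
#' is computed from the fit; a plateau at or below 15 is flagged
#' unreachable (`Inf`).
#'
#' @param trace A [new_fluor_trace()] recovery (I(0) = 0 after
#'   correction).
#' @return A `fit_result` with `model = "one_phase_association"`,
#'   `params` (`k`, `plateau`), and `t_q` holding `t15`.
#' @export
fit_recovery <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (length(trace$t) < 5) abort_input("need at least 5 points to fit")
  tt <- trace$t - trace$t[1]
  I <- trace$I
  plateau0 <- max(mean(utils::tail(I, 3)), max(I) * 0.5, 1e-6)
  y <- 1 - I / (plateau0 * 1.05)
  ok <- y > 0 & tt > 0
  k0 <- if (sum(ok) >= 2) {
    sl <- stats::coef(stats::lm(log(y[ok]) ~ tt[ok]))[2]
    if (is.finite(sl) && sl < 0) unname(-sl) else 1 / max(tt)
  } else 1 / max(tt)
  fit <- lm_curve_fit(
    par = c(k = k0, plateau = plateau0),
    lower = c(k = 1e-10, plateau = 1e-10),
    resid_fn = function(p) I - p[["plateau"]] * (1 - exp(-p[["k"]] * tt)))
  if (is.null(fit)) {
    warning("one-phase association fit did not converge", call. = FALSE)
    out <- new_fit_result("one_phase_association",
                          params = c(k = NA_real_, plateau = NA_real_),
                          residual_norm = NA_real_, converged = FALSE)
    out$t_q <- c(t15 = NA_real_)
    return(out)
  }
  out <- new_fit_result("one_phase_association",
                        params = c(k = fit$par[["k"]],
                                   plateau = fit$par[["plateau"]]),
                        residual_norm = fit$residual_norm,
                        converged = TRUE)
  out$t_q <- c(t15 = time_to_recovery(out, 15))
  out
}

#' Time for a fitted recovery to regain a given percentage
#'
#' @param fit A `fit_result` from [fit_recovery()].
#' @param pct Percentage points of fluorescence to recover (default 15).
#' @return Seconds; `Inf` if the fitted plateau lies at or below `pct`.
#' @export
time_to_recovery <- function(fit, pct = 15) {
  stopifnot(inherits(fit, "fit_result"), fit$model == "one_phase_association")
  p <- fit$params
  if (!is.finite(p[["k"]]) || p[["plateau"]] <= pct) return(Inf)
  -log(1 - pct / p[["plateau"]]) / p[["k"]]
}
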