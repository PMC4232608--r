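#' Stochastic mother-cell simulator of ERC accumulation and lifespan
#'
#' Mother-centric model of replicative ageing driven by DNA-circle
#' accumulation.  Per division: (i) if the mother already holds
#' `T_death` or more circles she senesces before budding; (ii) every
#' circle replicates and each of the two copies stays in the mother
#' independently with probability `rho` (the per-copy retention
#' fidelity); (iii) a new circle is excised with probability `f_form`;
#' (iv) the nuclear-pore pool grows by a fraction `npc_growth` and is
#' split between mother and bud with mother share
#' `s0 + min(kappa * C, b_max) * (fidelity - s0)` — circle-bound pores
#' (a saturating fraction of the pool) are retained with high fidelity,
#' unbound pores with the baseline asymmetry `s0`.  Expected circle
#' counts follow `E[C_{g+1}] = 2 * rho * E[C_g] + f_form` while the
#' mother lives.
#'
#' Per mother, the whole circle-formation sequence is drawn up-front
#' from a mother-specific substream, so cohorts simulated at different
#' retention or death parameters share their formation histories; this
#' common-random-number coupling makes parameter scans far less noisy.
#'
#' @param preset An `"ageing"` family [preset()].
#' @param n_mothers Cohort size.
#' @param seed Seed; defaults to the preset's.
#' @param init_circles Circles present at birth (default 0).
#' @return An `ageing_cohort`: list with `lifespans` (completed
#'   divisions), `died` (FALSE = still alive at `max_gen`), `divisions`
#'   (per-division data frame: `mother`, `age`, `circles`,
#'   `npc_mother`, `npc_bud`, `share`), `g1` (post-division snapshots:
#'   `mother`, `age`, `circles`, `npc_total`, `radius_um`), plus the
#'   preset and seed.
#' @examples
#' coh <- simulate_cohort(preset("ageing", "wt"), 20)
#' survival_summary(coh)$median
#' @export
simulate_cohort <- function(preset, n_mothers, seed = preset$seed,
                            init_circles = 0L) {
  stopifnot(inherits(preset, "generator_preset"))
  p <- preset$params
  if (p$rho < 0 || p$rho > 1) abort_input("rho must lie in [0, 1]")
  if (p$T_death < 2) abort_input("T_death must be >= 2")
  res <- lapply(seq_len(n_mothers), function(m)
    simulate_mother(p, derive_seed(seed, paste0("mother", m)), m,
                    init_circles))
  cohort <- list(
    lifespans = vapply(res, `[[`, numeric(1), "lifespan"),
    died = vapply(res, `[[`, logical(1), "died"),
    divisions = do.call(rbind, lapply(res, `[[`, "divisions")),
    g1 = do.call(rbind, lapply(res, `[[`, "g1")),
    preset = preset, seed = seed)
  class(cohort) <- "ageing_cohort"
  cohort
}

simulate_mother <- function(p, seed, mother_id, init_circles) {
  with_seed(seed, {
    G <- p$max_gen
    u_form <- stats::runif(G)  # drawn first: shared across parameter scans
    C <- as.integer(init_circles)
    N <- p$npc0
    age <- circ <- share_v <- npc_m <- npc_b <- numeric(G)
    g1_circ <- g1_npc <- numeric(G)
    lifespan <- G
    died <- FALSE
    for (g in seq_len(G)) {
      if (C >= p$T_death) {
        lifespan <- g - 1L
        died <- TRUE
        break
      }
      bound <- min(p$kappa * C, p$b_max)
      share <- p$s0 + bound * (p$fidelity - p$s0)
      total <- N * (1 + p$npc_growth)
      keepN <- share * total

      age[g] <- g
      circ[g] <- C
      share_v[g] <- share
      npc_m[g] <- keepN
      npc_b[g] <- total - keepN

      C <- stats::rbinom(1L, 2L * C, p$rho) + (u_form[g] < p$f_form)
      N <- keepN
      g1_circ[g] <- C
      g1_npc[g] <- N
    }
    lived <- seq_len(if (died) lifespan else G)
    list(lifespan = lifespan, died = died,
         divisions = data.frame(mother = mother_id, age = age[lived],
                                circles = circ[lived], share = share_v[lived],
                                npc_mother = npc_m[lived],
                                npc_bud = npc_b[lived]),
         g1 = data.frame(mother = mother_id, age = lived,
                         circles = g1_circ[lived], npc_total = g1_npc[lived],
                         radius_um = (g1_npc[lived] / p$npc0)^(1 / 3)))
  })
}

#' Survival summary of a simulated cohort
#'
#' @param cohort An `ageing_cohort`, or a numeric vector of lifespans.
#' @return A `survival_summary`: list with `median` (lower median on
#'   ties, the survival-curve crossing of 0.5), `curve` (data frame
#'   `age`, `surviving`), `n` and `label`.
#' @export
survival_summary <- function(cohort) {
  ls <- if (inherits(cohort, "ageing_cohort")) cohort$lifespans else cohort
  if (!length(ls)) abort_input("empty cohort")
  if (any(ls < 1)) abort_input("lifespans must be >= 1")
  srt <- sort(ls)
  med <- srt[ceiling(length(srt) / 2)]
  ages <- 0:max(ls)
  curve <- data.frame(age = ages,
                      surviving = vapply(ages, function(a) mean(ls >= a),
                                         numeric(1)))
  label <- if (inherits(cohort, "ageing_cohort")) cohort$preset$name else ""
  structure(list(median = med, curve = curve, n = length(ls), label = label),
            class = "survival_summary")
}

#' @export
print.survival_summary <- function(x, ...) {
  cat(sprintf("<survival_summary> %s n = %d, median lifespan = %g generations\n",
              x$label, x$n, x$median))
  invisible(x)
}

#' Log-rank (Mantel-Cox) comparison of two cohorts
#'
#' @param a,b `ageing_cohort`s or numeric lifespan vectors.
#' @return List with `chisq`, `df`, `p_value`, and the two medians.
#' @export
logrank_compare <- function(a, b) {
  la <- if (inherits(a, "ageing_cohort")) a$lifespans else a
  lb <- if (inherits(b, "ageing_cohort")) b$lifespans else b
  da <- if (inherits(a, "ageing_cohort")) a$died else rep(TRUE, length(la))
  db <- if (inherits(b, "ageing_cohort")) b$died else rep(TRUE, length(lb))
  time <- c(la, lb)
  status <- as.integer(c(da, db))
  grp <- rep(c("a", "b"), c(length(la), length(lb)))
  sd_ <- survival::survdiff(survival::Surv(time, status) ~ grp)
  df <- length(sd_$n) - 1
  list(chisq = sd_$chisq, df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       median_a = survival_summary(la)$median,
       median_b = survival_summary(lb)$median)
}

#' Scan lifespan and accumulation against retention fidelity
#'
#' Simulates one cohort per value of `rho` on a shared seed stream and
#' summarizes median lifespan plus the age profiles of circle counts
#' and NPC mother share.  A non-monotone median-lifespan sequence is
#' flagged (`monotone = FALSE`), since under the model lower retention
#' fidelity can only delay accumulation.
#'
#' @param preset Base `"ageing"` preset.
#' @param rho_grid Retention-fidelity values to scan.
#' @param n_mothers Mothers per cohort (default 200).
#' @param seed Base seed shared by all grid points.
#' @param ages Ages at which profiles are evaluated.
#' @return List with `table` (data frame `rho`, `median_lifespan`),
#'   `profiles` (per-rho data frames: `age`, `mean_circles`,
#'   `mean_share`), `spearman` (rank correlation of median lifespan with
#'   rho) and `monotone`.
#' @export
retention_sensitivity_scan <- function(preset, rho_grid, n_mothers = 200,
                                       seed = preset$seed, ages = 1:40) {
  rows <- list()
  profiles <- list()
  for (i in seq_along(rho_grid)) {
    pr <- preset
    pr$params$rho <- rho_grid[i]
    coh <- simulate_cohort(pr, n_mothers, seed = seed)
    med <- survival_summary(coh)$median
    rows[[i]] <- data.frame(rho = rho_grid[i], median_lifespan = med)
    dv <- coh$divisions
    profiles[[i]] <- data.frame(
      age = ages,
      mean_circles = vapply(ages, function(a)
        if (any(dv$age == a)) mean(dv$circles[dv$age == a]) else NA_real_,
        numeric(1)),
      mean_share = vapply(ages, function(a)
        if (any(dv$age == a)) mean(dv$share[dv$age == a]) else NA_real_,
        numeric(1)))
  }
  table <- do.call(rbind, rows)
  names(profiles) <- as.character(rho_grid)
  spearman <- if (nrow(table) >= 3 && stats::sd(table$median_lifespan) > 0) {
    stats::cor(table$rho, table$median_lifespan, method = "spearman")
  } else NA_real_
  list(table = table, profiles = profiles, spearman = spearman,
       monotone = all(diff(table$median_lifespan) <= 0))
}

#' Calibrate the ageing preset to a target median lifespan
#'
#' Fixes the retention fidelity from the measured propagation frequency
#' (`rho = 1 - pf/100`) and searches the circle-formation probability
#' `f_form` (or, when `f_form` is supplied, the death threshold
#' `T_death`) until the simulated median lifespan matches the target.
#' The search is a deterministic bisection on a fixed seed policy;
#' median lifespan is monotone decreasing in `f_form` and increasing in
#' `T_death`.
#'
#' @param target_median Target median lifespan (generations).
#' @param pf Propagation frequency (percent) fixing `rho`; ignored when
#'   `rho` is given.
#' @param rho Retention fidelity; overrides `pf`.
#' @param preset Base `"ageing"` preset to calibrate.
#' @param f_form Fix the formation probability and search `T_death`
#'   instead (powers of two between 4 and 2^16).
#' @param n_mothers Mothers per evaluation (default 400).
#' @param seed Seed policy for all evaluations.
#' @param tol Acceptable |achieved - target| (generations).
#' @return List with `preset` (calibrated), `achieved_median`,
#'   `target_median`, `feasible` and the search `trace`; infeasible
#'   targets return `feasible = FALSE` with the closest bound tried.
#' @export
calibrate_to_wt <- function(target_median, pf = NULL, rho = NULL,
                            preset = NULL, f_form = NULL,
                            n_mothers = 400, seed = 1L, tol = 1) {
  if (is.null(preset)) preset <- preset("ageing", "wt", seed = seed)
  if (is.null(rho)) rho <- if (!is.null(pf)) 1 - pf / 100 else preset$params$rho
  preset$params$rho <- rho
  med_at <- function(pr) {
    coh <- simulate_cohort(pr, n_mothers, seed = derive_seed(seed, "calib"))
    survival_summary(coh)$median
  }
  trace <- list()
  if (is.null(f_form)) {
    # bisect log(f_form): median decreases with formation rate
    lo <- 1e-4; hi <- 1
    pr <- preset
    pr$params$f_form <- lo
    m_lo <- med_at(pr)           # longest lifespans
    pr$params$f_form <- hi
    m_hi <- med_at(pr)           # shortest
    if (target_median > m_lo || target_median < m_hi) {
      return(list(preset = preset, achieved_median = NA_real_,
                  target_median = target_median, feasible = FALSE,
                  trace = data.frame(f_form = c(lo, hi),
                                     median = c(m_lo, m_hi))))
    }
    for (it in 1:24) {
      mid <- sqrt(lo * hi)
      pr$params$f_form <- mid
      m <- med_at(pr)
      trace[[it]] <- data.frame(f_form = mid, median = m)
      if (abs(m - target_median) <= tol) break
      if (m > target_median) lo <- mid else hi <- mid
    }
    preset$params$f_form <- pr$params$f_form
    achieved <- m
  } else {
    preset$params$f_form <- f_form
    exps <- 2:16
    meds <- rep(NA_real_, length(exps))
    for (i in seq_along(exps)) {
      pr <- preset
      pr$params$T_death <- 2^exps[i]
      meds[i] <- med_at(pr)
      trace[[i]] <- data.frame(T_death = 2^exps[i], median = meds[i])
      if (meds[i] >= target_median) break
    }
    best <- which.min(abs(meds - target_median))
    preset$params$T_death <- 2^exps[best]
    achieved <- meds[best]
    if (abs(achieved - target_median) > max(tol, 2)) {
      return(list(preset = preset, achieved_median = achieved,
                  target_median = target_median, feasible = FALSE,
                  trace = do.call(rbind, trace)))
    }
  }
  list(preset = preset, achieved_median = achieved,
       target_median = target_median,
       feasible = abs(achieved - target_median) <= max(tol, 2),
       trace = do.call(rbind, trace))
}
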