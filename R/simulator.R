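#' Study design for operating-characteristic simulation
#'
#' @param structure A [trial_structure()].
#' @param scenarios List of [scenario()] objects covering all baskets.
#' @param cutoffs Named list of [cutoff_set()] objects, one per approach
#'   in `approaches`.
#' @param reps Simulated datasets per scenario.
#' @param seed Master seed; each (scenario, replicate) runs in its own
#'   substream so any single replicate can be replayed exactly.
#' @param approaches Character subset of IND, UNPL, PL1a, PL2a.
#' @param q0,q1 Null and target response rates.
#' @return An object of class `study_design`.
#' @export
study_design <- function(structure, scenarios, cutoffs, reps,
                         seed = 1L,
                         approaches = c("IND", "UNPL", "PL1a", "PL2a"),
                         q0 = 0.2, q1 = 0.4) {
  stopifnot(inherits(structure, "trial_structure"), reps >= 1)
  approaches <- match.arg(approaches, several.ok = TRUE)
  missing_cut <- setdiff(approaches, names(cutoffs))
  if (length(missing_cut))
    stop("no cut-off set supplied for approach(es): ",
         paste(missing_cut, collapse = ", "), call. = FALSE)
  K <- structure$K0 + structure$K_new
  for (s in scenarios)
    if (length(s$p) != K)
      stop("scenario '", s$name, "' does not cover all ", K, " baskets",
           call. = FALSE)
  base::structure(
    list(structure = structure, scenarios = scenarios,
         cutoffs = cutoffs, reps = as.integer(reps),
         seed = as.integer(seed), approaches = approaches,
         q0 = q0, q1 = q1),
    class = "study_design")
}

# run the shared analysis fits for one dataset and return the per-approach
# exceedance-probability matrix (approach x basket) plus posterior means.
# All approaches see the same dataset and the fits are shared: IND and
# PL2a use the same existing-basket fit, UNPL and PL1a the same
# all-basket fit (common random numbers).
analyse_shared <- function(dat, structure, config, ms, approaches) {
  K0 <- structure$K0
  K <- K0 + structure$K_new
  idx_ex <- seq_len(K0)
  idx_new <- setdiff(seq_len(K), idx_ex)
  need_k0 <- any(approaches %in% c("IND", "PL2a")) || K == K0
  need_all <- any(approaches %in% c("UNPL", "PL1a", "PL2a")) && K > K0
  need_ind <- "IND" %in% approaches && K > K0

  fit_k0 <- if (need_k0) fit_exnex(subset_baskets(dat, idx_ex), config, ms)
  fit_all <- if (need_all) fit_exnex(dat, config, ms)
  fit_ind <- if (need_ind)
    fit_independent(subset_baskets(dat, idx_new), config, ms)

  exceed <- est <- matrix(NA_real_, length(approaches), K,
                          dimnames = list(approaches, NULL))
  for (a in approaches) {
    exceed[a, ] <- switch(a,
      IND = if (K > K0) c(fit_k0$exceed_prob, fit_ind$exceed_prob)
            else fit_k0$exceed_prob,
      UNPL = ,
      PL1a = if (K > K0) fit_all$exceed_prob else fit_k0$exceed_prob,
      PL2a = if (K > K0) c(fit_k0$exceed_prob,
                           fit_all$exceed_prob[idx_new])
             else fit_k0$exceed_prob)
    est[a, ] <- switch(a,
      IND = if (K > K0) c(fit_k0$post_mean, fit_ind$post_mean)
            else fit_k0$post_mean,
      UNPL = ,
      PL1a = if (K > K0) fit_all$post_mean else fit_k0$post_mean,
      PL2a = if (K > K0) c(fit_k0$post_mean, fit_all$post_mean[idx_new])
             else fit_k0$post_mean)
  }
  list(exceed = exceed, est = est)
}

#' Fixed-scenario operating characteristics
#'
#' For each scenario and replicate, simulates a dataset, analyses it
#' under every requested approach (approaches share the dataset and,
#' where their analysis models coincide, the posterior draws), applies
#' the approach's cut-offs and accumulates rejection indicators. Reports
#' per-basket rejection proportions, type I error (baskets at `q0`),
#' power (baskets at `q1`), family-wise error rate among null baskets,
#' the proportion of datasets with every basket decided correctly, and
#' posterior-mean estimation summaries, with Monte Carlo standard errors.
#'
#' @param design A [study_design()].
#' @param config An [exnex_config()].
#' @param mcmc An [mcmc_settings()] for the per-replicate fits.
#' @return An object of class `basket_oc`; `as.data.frame()` gives a
#'   tidy table with columns approach, scenario, basket, metric, value,
#'   mc_se.
#' @export
run_fixed_study <- function(design, config = exnex_config(),
                            mcmc = mcmc_settings(n_chains = 1,
                                                 n_warmup = 500,
                                                 n_samples = 2500)) {
  stopifnot(inherits(design, "study_design"))
  st <- design$structure
  K <- st$K0 + st$K_new
  ms <- mcmc_streamed(mcmc)
  apps <- design$approaches
  reps <- design$reps

  cells <- list()
  for (scen in design$scenarios) {
    h <- scenario_hash(scen)
    rej <- array(0, c(length(apps), K), dimnames = list(apps, NULL))
    est_sum <- est_sq <- rej
    fwer_n <- all_ok <- stats::setNames(numeric(length(apps)), apps)
    null_k <- which(abs(scen$p - design$q0) < 1e-9)
    eff_k <- which(scen$p > design$q0)
    for (r in seq_len(reps)) {
      set.seed(substream_seed(design$seed, h, r))
      dat <- generate_trial(scen)
      res <- analyse_shared(dat, st, config, ms, apps)
      for (a in apps) {
        dec <- decide(res$exceed[a, ], design$cutoffs[[a]])
        rej[a, ] <- rej[a, ] + dec$reject
        est_sum[a, ] <- est_sum[a, ] + res$est[a, ]
        est_sq[a, ] <- est_sq[a, ] + res$est[a, ]^2
        if (length(null_k) && any(dec$reject[null_k]))
          fwer_n[a] <- fwer_n[a] + 1
        if (all(dec$reject == (scen$p > design$q0)))
          all_ok[a] <- all_ok[a] + 1
      }
    }
    pct <- rej / reps
    cells[[scen$name]] <- list(
      scenario = scen,
      pct_reject = pct,
      type1 = pct[, null_k, drop = FALSE],
      power = pct[, which(abs(scen$p - design$q1) < 1e-9), drop = FALSE],
      fwer = if (length(null_k)) fwer_n / reps else
        stats::setNames(rep(NA_real_, length(apps)), apps),
      all_correct = all_ok / reps,
      est_mean = est_sum / reps,
      est_sd = sqrt(pmax(est_sq / reps - (est_sum / reps)^2, 0) *
                      reps / max(1, reps - 1)),
      mc_se = sqrt(pct * (1 - pct) / reps),
      null_baskets = null_k, effective_baskets = eff_k,
      reps = reps)
  }
  structure(list(cells = cells, design = design), class = "basket_oc")
}

#' @export
as.data.frame.basket_oc <- function(x, ...) {
  out <- list()
  for (nm in names(x$cells)) {
    cell <- x$cells[[nm]]
    apps <- rownames(cell$pct_reject)
    K <- ncol(cell$pct_reject)
    for (a in apps) {
      out[[length(out) + 1L]] <- data.frame(
        approach = a, scenario = nm, basket = seq_len(K),
        metric = "pct_reject", value = cell$pct_reject[a, ],
        mc_se = cell$mc_se[a, ])
      out[[length(out) + 1L]] <- data.frame(
        approach = a, scenario = nm, basket = seq_len(K),
        metric = "est_mean", value = cell$est_mean[a, ],
        mc_se = cell$est_sd[a, ] / sqrt(cell$reps))
      out[[length(out) + 1L]] <- data.frame(
        approach = a, scenario = nm, basket = NA_integer_,
        metric = c("fwer", "all_correct"),
        value = c(cell$fwer[a], cell$all_correct[a]),
        mc_se = c(sqrt(cell$fwer[a] * (1 - cell$fwer[a]) / cell$reps),
                  sqrt(cell$all_correct[a] * (1 - cell$all_correct[a]) /
                         cell$reps)))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.basket_oc <- function(x, ...) {
  for (nm in names(x$cells)) {
    cell <- x$cells[[nm]]
    cat(nm, " (p = ", paste(cell$scenario$p, collapse = ", "), "), ",
        cell$reps, " reps\n", sep = "")
    print(round(cell$pct_reject, 3))
  }
  invisible(x)
}

#' Gaps between observed and nominal operating characteristics
#'
#' Summarises a fixed-scenario study against nominal targets: the mean
#' rejection rate over null existing baskets minus the nominal type I
#' error, the mean over effective existing baskets minus the nominal
#' power, and the new basket's gap (against whichever target applies to
#' its true rate). Scenarios with no basket in a category report `NA`
#' for that gap, never zero.
#'
#' @param oc A `basket_oc` from [run_fixed_study()].
#' @param nominal_type1 Nominal basket-wise type I error rate.
#' @param nominal_power Nominal power.
#' @return A data frame with one row per (approach, scenario).
#' @export
summarise_vs_nominal <- function(oc, nominal_type1 = 0.10,
                                 nominal_power = 0.80) {
  stopifnot(inherits(oc, "basket_oc"))
  st <- oc$design$structure
  K0 <- st$K0
  rows <- list()
  for (nm in names(oc$cells)) {
    cell <- oc$cells[[nm]]
    scen <- cell$scenario
    null_ex <- intersect(cell$null_baskets, seq_len(K0))
    eff_ex <- intersect(cell$effective_baskets, seq_len(K0))
    new_idx <- setdiff(seq_along(scen$p), seq_len(K0))
    for (a in rownames(cell$pct_reject)) {
      err_gap <- if (length(null_ex))
        mean(cell$pct_reject[a, null_ex]) - nominal_type1 else NA_real_
      pow_gap <- if (length(eff_ex))
        mean(cell$pct_reject[a, eff_ex]) - nominal_power else NA_real_
      new_gap <- if (length(new_idx)) {
        target <- if (scen$p[new_idx[1]] > oc$design$q0)
          nominal_power else nominal_type1
        mean(cell$pct_reject[a, new_idx]) - target
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        approach = a, scenario = nm,
        existing_error_gap = err_gap, existing_power_gap = pow_gap,
        new_basket_gap = new_gap)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Random-scenario specification
#'
#' In the random-scenario study the existing baskets' true rates are
#' fixed while the new basket's rate is drawn uniformly from an interval
#' for every simulated trial.
#'
#' @param fixed_p_existing True rates for the existing baskets.
#' @param new_interval Length-2 vector `(lo, hi)` with
#'   `0 <= lo <= hi <= 1`; the new basket's rate is
#'   `Uniform(lo, hi)`. A degenerate interval (`lo == hi`) is treated as
#'   a fixed rate.
#' @param n_draws Number of random scenarios (one dataset each).
#' @param seed Master seed.
#' @return An object of class `random_scenario_spec`.
#' @export
random_scenario_spec <- function(fixed_p_existing, new_interval,
                                 n_draws, seed = 1L) {
  stopifnot(length(new_interval) == 2, new_interval[1] >= 0,
            new_interval[2] <= 1, new_interval[1] <= new_interval[2],
            n_draws >= 1)
  if (new_interval[1] == new_interval[2])
    message("degenerate interval: new basket rate fixed at ",
            new_interval[1])
  structure(
    list(fixed_p_existing = fixed_p_existing,
         new_interval = new_interval, n_draws = as.integer(n_draws),
         seed = as.integer(seed)),
    class = "random_scenario_spec")
}

#' Pairwise decision discrepancies under random scenarios
#'
#' Draws `n_draws` random scenarios (new basket rate uniform on the
#' spec's interval), simulates one dataset per scenario, analyses it
#' under every approach at common random numbers, and records
#' basket-level decision disagreements between each approach pair. A
#' basket's correct decision is "reject" precisely when its true rate
#' exceeds `q0`, so in any disagreement exactly one side is correct;
#' records where both sides are wrong are excluded as a safeguard
#' (a no-op under this labelling).
#'
#' @param spec A [random_scenario_spec()].
#' @param design A [study_design()] providing structure, cut-offs and
#'   approaches (its scenario list and reps are ignored).
#' @param config An [exnex_config()].
#' @param mcmc An [mcmc_settings()].
#' @return A data frame of class `discrepancy_result`: one row per
#'   ordered approach pair with `n_discrepant` and `diff_prop_correct`
#'   (row approach minus column approach).
#' @export
run_random_study <- function(spec, design, config = exnex_config(),
                             mcmc = mcmc_settings(n_chains = 1,
                                                  n_warmup = 500,
                                                  n_samples = 2500)) {
  stopifnot(inherits(spec, "random_scenario_spec"),
            inherits(design, "study_design"))
  st <- design$structure
  if (st$K_new != 1L)
    stop("the random-scenario study requires exactly one new basket",
         call. = FALSE)
  if (length(spec$fixed_p_existing) != st$K0)
    stop("`fixed_p_existing` must cover the ", st$K0,
         " existing baskets", call. = FALSE)
  K <- st$K0 + 1L
  n_all <- c(st$n_existing, st$n_new)
  apps <- design$approaches
  ms <- mcmc_streamed(mcmc)

  pairs <- utils::combn(apps, 2)
  n_disc <- corr_row <- corr_col <- stats::setNames(
    numeric(ncol(pairs)), apply(pairs, 2, paste, collapse = " vs "))

  for (i in seq_len(spec$n_draws)) {
    set.seed(substream_seed(spec$seed, 0, i))
    p5 <- stats::runif(1, spec$new_interval[1], spec$new_interval[2])
    p <- c(spec$fixed_p_existing, p5)
    scen <- scenario(p = p, n = n_all, name = sprintf("draw%06d", i))
    dat <- generate_trial(scen)
    res <- analyse_shared(dat, st, config, ms, apps)
    truth <- p > design$q0
    rejects <- matrix(FALSE, length(apps), K, dimnames = list(apps, NULL))
    for (a in apps)
      rejects[a, ] <- decide(res$exceed[a, ], design$cutoffs[[a]])$reject
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      disc <- which(rejects[a, ] != rejects[b, ])
      for (k in disc) {
        a_ok <- rejects[a, k] == truth[k]
        b_ok <- rejects[b, k] == truth[k]
        if (!a_ok && !b_ok) next  # both wrong: excluded
        n_disc[j] <- n_disc[j] + 1
        if (a_ok) corr_row[j] <- corr_row[j] + 1
        if (b_ok) corr_col[j] <- corr_col[j] + 1
      }
    }
  }
  out <- data.frame(
    approach_row = pairs[1, ], approach_col = pairs[2, ],
    n_discrepant = as.integer(n_disc),
    diff_prop_correct = ifelse(n_disc > 0,
                               (corr_row - corr_col) / n_disc, NA_real_))
  class(out) <- c("discrepancy_result", class(out))
  out
}
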