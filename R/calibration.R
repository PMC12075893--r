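#' A calibration/simulation scenario
#'
#' A vector of true response rates with matching sample sizes and an
#' integer weight. Weights only matter in robust calibration, where they
#' give the number of copies of each posterior quantity a scenario
#' contributes to the pooled calibration store.
#'
#' @param p Numeric vector of true response rates.
#' @param n Integer vector of sample sizes, same length as `p`.
#' @param weight Positive integer scenario weight.
#' @param name Optional scenario label.
#' @return An object of class `basket_scenario`.
#' @examples
#' scenario(p = c(0.4, 0.2, 0.2, 0.2, 0.2), n = c(24, 24, 24, 24, 14))
#' @export
scenario <- function(p, n, weight = 1L, name = NULL) {
  if (length(p) != length(n) || length(p) < 1L)
    stop("`p` and `n` must have equal, positive length", call. = FALSE)
  if (any(p < 0) || any(p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  if (any(n < 1) || any(n != round(n)))
    stop("`n` must contain positive integers", call. = FALSE)
  if (length(weight) != 1L || weight < 1 || weight != round(weight))
    stop("`weight` must be a positive integer", call. = FALSE)
  structure(
    list(p = as.numeric(p), n = as.integer(n),
         weight = as.integer(weight),
         name = name %||% paste0("scenario(",
                                 paste(p, collapse = ","), ")")),
    class = "basket_scenario")
}

#' Calibration specification
#'
#' @param scenarios List of [scenario()] objects, all with the same
#'   number of baskets (the baskets of the calibration model).
#' @param R Replications per scenario per unit weight.
#' @param alpha Nominal level; cut-offs are the empirical
#'   `(1 - alpha)`-quantile of the pooled calibration store.
#' @param q0 Null response rate defining the type I error condition
#'   `p[k] == q0`.
#' @param model Analysis model fitted to each simulated dataset:
#'   `"exnex"` or `"independent"`.
#' @param seed Master seed; each (scenario, replicate) pair draws from
#'   its own recorded substream.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(scenarios, R, alpha = 0.10, q0 = 0.2,
                             model = c("exnex", "independent"),
                             seed = 1L) {
  model <- match.arg(model)
  if (!length(scenarios) || !all(vapply(scenarios, inherits, TRUE,
                                        "basket_scenario")))
    stop("`scenarios` must be a non-empty list of scenario objects",
         call. = FALSE)
  Ks <- vapply(scenarios, function(s) length(s$p), 1L)
  if (length(unique(Ks)) != 1L)
    stop("all scenarios must cover the same number of baskets",
         call. = FALSE)
  stopifnot(R >= 1, alpha > 0, alpha < 1, q0 > 0, q0 < 1)
  structure(
    list(scenarios = scenarios, R = as.integer(R), alpha = alpha,
         q0 = q0, model = model, seed = as.integer(seed)),
    class = "calibration_spec")
}

#' Simulate one trial dataset from a scenario
#'
#' Draws `y[k] ~ Binomial(n[k], p[k])` independently across baskets,
#' using the current R RNG state.
#'
#' @param scen A [scenario()].
#' @return A [basket_data()].
#' @examples
#' set.seed(1)
#' generate_trial(scenario(p = rep(0.2, 5), n = c(24, 24, 24, 24, 14)))
#' @export
generate_trial <- function(scen) {
  stopifnot(inherits(scen, "basket_scenario"))
  basket_data(stats::rbinom(length(scen$p), scen$n, scen$p), scen$n)
}

#' Robust calibration of efficacy cut-offs across scenarios
#'
#' Calibrates the posterior-probability cut-offs so that the basket-wise
#' type I error rate is controlled at `alpha` on (weighted) average
#' across the supplied scenarios, rather than only under the global
#' null. For each scenario, `R` datasets are simulated and the analysis
#' model fitted; for every basket whose true rate equals `q0` (the only
#' baskets where a type I error is defined), `weight` copies of its
#' posterior exceedance probability are appended to that basket's store.
#' Stores of baskets sharing a sample size are pooled, and the cut-off
#' for each sample-size class is the empirical `(1 - alpha)`-quantile of
#' the pooled store, taken as the order statistic at index
#' `ceiling((1 - alpha) * N)`. Baskets with equal sample sizes therefore
#' receive identical cut-offs by construction. Scenarios with no null
#' basket contribute nothing and are skipped with a message.
#'
#' @param spec A [calibration_spec()].
#' @param config An [exnex_config()].
#' @param mcmc An [mcmc_settings()]; its seed field is ignored in favour
#'   of the spec's per-replicate substreams.
#' @param structure Optional [trial_structure()] used to split the
#'   per-basket cut-offs into existing and new entries; when `NULL`, all
#'   baskets are reported as existing.
#' @return A [cutoff_set()] with provenance.
#' @export
rcap_calibrate <- function(spec, config = exnex_config(),
                           mcmc = mcmc_settings(), structure = NULL) {
  stopifnot(inherits(spec, "calibration_spec"))
  K <- length(spec$scenarios[[1]]$p)
  n_ref <- spec$scenarios[[1]]$n
  for (s in spec$scenarios)
    if (!identical(s$n, n_ref))
      stop("all scenarios must share the same sample sizes", call. = FALSE)

  ms <- mcmc_streamed(mcmc)
  fitter <- if (spec$model == "exnex") fit_exnex else fit_independent

  stores <- vector("list", length(spec$scenarios))
  for (m in seq_along(spec$scenarios)) {
    scen <- spec$scenarios[[m]]
    null_idx <- which(abs(scen$p - spec$q0) < 1e-9)
    if (!length(null_idx)) {
      message("scenario '", scen$name,
              "' has no basket at the null rate; it contributes nothing ",
              "to type I error calibration and is skipped")
      next
    }
    h <- scenario_hash(scen)
    Qm <- matrix(NA_real_, spec$R, length(null_idx))
    for (r in seq_len(spec$R)) {
      set.seed(substream_seed(spec$seed, h, r))
      fit <- fitter(generate_trial(scen), config, ms)
      Qm[r, ] <- fit$exceed_prob[null_idx]
    }
    stores[[m]] <- list(idx = null_idx, Q = Qm, weight = scen$weight)
  }
  if (all(vapply(stores, is.null, TRUE)))
    stop("no scenario contains a basket at the null rate q0 = ", spec$q0,
         call. = FALSE)

  # pool per sample-size class, then one order-statistic quantile per class
  delta_k <- rep(NA_real_, K)
  for (nn in unique(n_ref)) {
    class_idx <- which(n_ref == nn)
    pool <- unlist(lapply(stores, function(st) {
      if (is.null(st)) return(NULL)
      cols <- which(st$idx %in% class_idx)
      if (!length(cols)) return(NULL)
      rep(as.numeric(st$Q[, cols]), st$weight)
    }))
    if (is.null(pool) || !length(pool))
      stop("no scenario nulls any basket with sample size ", nn,
           "; cannot calibrate that sample-size class", call. = FALSE)
    delta_k[class_idx] <-
      sort(pool)[ceiling((1 - spec$alpha) * length(pool))]
  }

  prov <- list(method = "rcap", model = spec$model, R = spec$R,
               alpha = spec$alpha, q0 = spec$q0, seed = spec$seed,
               scenarios = lapply(spec$scenarios, function(s)
                 list(name = s$name, p = s$p, n = s$n,
                      weight = s$weight)))
  if (is.null(structure)) {
    cutoff_set(delta_existing = delta_k, provenance = prov)
  } else {
    K0 <- structure$K0
    cutoff_set(delta_existing = delta_k[seq_len(K0)],
               delta_new = delta_k[setdiff(seq_len(K), seq_len(K0))],
               provenance = prov)
  }
}

#' Classical calibration under the global null
#'
#' The traditional single-scenario calibration: every basket's true rate
#' is set to `q0` and the cut-off is the `(1 - alpha)`-quantile of the
#' null exceedance probabilities. Implemented as [rcap_calibrate()] with
#' a single all-null scenario (the two are identical when the robust
#' procedure is given only the global null).
#'
#' @param spec A [calibration_spec()]; only its sample sizes, `R`,
#'   `alpha`, `q0`, `model` and `seed` are used — the scenario list is
#'   replaced by the all-null scenario.
#' @inheritParams rcap_calibrate
#' @return A [cutoff_set()].
#' @export
calibrate_global_null <- function(spec, config = exnex_config(),
                                  mcmc = mcmc_settings(),
                                  structure = NULL) {
  stopifnot(inherits(spec, "calibration_spec"))
  n_ref <- spec$scenarios[[1]]$n
  gn <- scenario(p = rep(spec$q0, length(n_ref)), n = n_ref,
                 name = "global null")
  spec$scenarios <- list(gn)
  out <- rcap_calibrate(spec, config, mcmc, structure)
  out$provenance$method <- "global_null"
  out
}

#' Match a new basket's cut-off by sample size
#'
#' Under the unplanned-addition (UNPL) approach the new basket inherits
#' the cut-off of the existing basket whose sample size is closest to its
#' own; ties go to the smallest basket index. When all existing sample
#' sizes are equal this reduces to the shared existing cut-off.
#'
#' @param delta_existing Numeric vector of existing-basket cut-offs.
#' @param n_existing Integer vector of existing-basket sample sizes.
#' @param n_new Single sample size of the new basket.
#' @return The matched cut-off value.
#' @examples
#' match_cutoff_by_sample_size(c(0.85, 0.87, 0.90), c(10, 20, 30), 22)
#' @export
match_cutoff_by_sample_size <- function(delta_existing, n_existing,
                                        n_new) {
  if (!length(delta_existing))
    stop("`delta_existing` is empty", call. = FALSE)
  if (length(delta_existing) != length(n_existing))
    stop("`delta_existing` and `n_existing` must have equal length",
         call. = FALSE)
  delta_existing[which.min(abs(n_existing - n_new))]
}

#' Calibrate cut-offs for one basket-addition approach
#'
#' Runs the calibration model(s) each approach prescribes and assembles a
#' full [cutoff_set()] for the trial:
#'
#' * `IND` — existing cut-offs from EXNEX on the existing baskets; new
#'   cut-offs from the independent model on the new baskets alone.
#' * `UNPL` — existing cut-offs from EXNEX on the existing baskets
#'   (robust calibration uses existing-basket scenarios only); new
#'   baskets inherit by sample-size matching.
#' * `PL1a` — a single EXNEX calibration over all baskets yields both.
#' * `PL2a` — existing cut-offs as IND; new cut-offs from the
#'   all-basket EXNEX calibration.
#'
#' Scenarios covering all `K` baskets are projected onto the subset a
#' calibration model uses; scenarios may also be supplied already
#' restricted to the existing baskets (as UNPL's robust calibration
#' requires).
#'
#' @param approach One of `"IND"`, `"UNPL"`, `"PL1a"`, `"PL2a"`.
#' @param structure A [trial_structure()].
#' @param scenarios List of [scenario()] objects for robust calibration
#'   (ignored when `method = "global_null"`).
#' @param R Replications per scenario per unit weight.
#' @param alpha Nominal basket-wise type I error level.
#' @param config An [exnex_config()].
#' @param mcmc An [mcmc_settings()].
#' @param method `"global_null"` or `"rcap"`.
#' @param seed Master seed for the calibration substreams.
#' @return A [cutoff_set()].
#' @export
calibrate_approach <- function(approach, structure, scenarios = NULL,
                               R = 10000, alpha = 0.10,
                               config = exnex_config(),
                               mcmc = mcmc_settings(),
                               method = c("rcap", "global_null"),
                               seed = 1L) {
  approach <- match.arg(approach, c("IND", "UNPL", "PL1a", "PL2a"))
  method <- match.arg(method)
  stopifnot(inherits(structure, "trial_structure"))
  K0 <- structure$K0
  K <- K0 + structure$K_new
  n_all <- c(structure$n_existing, structure$n_new)
  q0 <- config$q0

  if (method == "rcap" && is.null(scenarios))
    stop("robust calibration requires a scenario list", call. = FALSE)

  project <- function(scen, idx)
    scenario(p = scen$p[idx], n = scen$n[idx], weight = scen$weight,
             name = scen$name)
  take <- function(scens, idx, label) {
    lapply(scens, function(s) {
      if (length(s$p) == K) project(s, idx)
      else if (length(s$p) == length(idx)) s
      else stop("scenario '", s$name, "' covers ", length(s$p),
                " baskets; expected ",
                paste(unique(c(K, length(idx))), collapse = " or "),
                " for the ", label, " calibration model", call. = FALSE)
    })
  }
  calib <- function(scens, model, target_structure = NULL) {
    sp <- calibration_spec(scens, R = R, alpha = alpha, q0 = q0,
                           model = model, seed = seed)
    if (method == "global_null")
      calibrate_global_null(sp, config, mcmc, target_structure)
    else rcap_calibrate(sp, config, mcmc, target_structure)
  }
  idx_ex <- seq_len(K0)
  idx_new <- setdiff(seq_len(K), idx_ex)
  # global-null calibration needs only sample sizes; synthesise the scenario
  if (method == "global_null" && is.null(scenarios))
    scenarios <- list(scenario(p = rep(q0, K), n = n_all,
                               name = "global null"))

  if (approach == "PL1a") {
    out <- calib(take(scenarios, seq_len(K), "all-basket"), "exnex",
                 structure)
  } else {
    ex_cal <- calib(take(scenarios, idx_ex, "existing-basket"), "exnex")
    d_ex <- ex_cal$delta_existing
    d_new <- switch(approach,
      IND = if (structure$K_new > 0)
        calib(take(scenarios, idx_new, "new-basket"),
              "independent")$delta_existing
        else numeric(),
      UNPL = vapply(structure$n_new, function(nn)
        match_cutoff_by_sample_size(d_ex, structure$n_existing, nn),
        numeric(1)),
      PL2a = if (structure$K_new > 0)
        calib(take(scenarios, seq_len(K), "all-basket"), "exnex",
              structure)$delta_new
        else numeric())
    out <- cutoff_set(d_ex, d_new,
                      provenance = ex_cal$provenance)
  }
  out$provenance$approach <- approach
  out$provenance$method <- method
  out
}
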