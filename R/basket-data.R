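#' Observed basket-trial data
#'
#' Container for the observed outcome of a basket trial with a binary
#' endpoint: per-basket response counts `y` out of sample sizes `n`.
#'
#' @param y Integer vector of response counts, one per basket.
#' @param n Integer vector of sample sizes, one per basket.
#' @param labels Optional character vector of basket names.
#'
#' @return An object of class `basket_data` with elements `y`, `n`,
#'   `labels` and `K` (the number of baskets).
#' @examples
#' basket_data(y = c(7, 4, 5, 9, 3), n = c(24, 24, 24, 24, 14))
#' @export
basket_data <- function(y, n, labels = NULL) {
  if (length(y) != length(n) || length(y) < 1L)
    stop("`y` and `n` must have equal, positive length", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(n)))
    stop("`y` and `n` must be finite", call. = FALSE)
  if (any(n < 1) || any(n != round(n)))
    stop("`n` must contain positive integers", call. = FALSE)
  if (any(y < 0) || any(y > n) || any(y != round(y)))
    stop("`y` must contain integers with 0 <= y[k] <= n[k]", call. = FALSE)
  if (is.null(labels)) labels <- paste0("basket", seq_along(y))
  if (length(labels) != length(y))
    stop("`labels` must match the number of baskets", call. = FALSE)
  structure(
    list(y = as.integer(y), n = as.integer(n), labels = labels,
         K = length(y)),
    class = "basket_data")
}

#' @export
print.basket_data <- function(x, ...) {
  cat("Basket trial data:", x$K, "baskets\n")
  print(data.frame(basket = x$labels, y = x$y, n = x$n,
                   rate = round(x$y / x$n, 3)), row.names = FALSE)
  invisible(x)
}

# slice a basket_data to a subset of baskets
subset_baskets <- function(data, idx) {
  basket_data(data$y[idx], data$n[idx], data$labels[idx])
}

#' NEX prior parameters from a plausible response rate
#'
#' The nonexchangeable (NEX) component of the EXNEX model gives basket `k`
#' its own prior on the logit response rate, `N(m_k, v2_k)`, derived from a
#' plausible guess `rho_k` of the true response rate:
#' `m_k = logit(rho_k)` and `v2_k = 1/rho_k + 1/(1 - rho_k)`, a weakly
#' informative choice whose variance corresponds to roughly one
#' observation's worth of information at rate `rho_k`.
#'
#' @param rho Numeric vector of plausible response rates, each in (0, 1).
#' @return A list of class `nex_prior` with numeric vectors `m` (prior
#'   means) and `v2` (prior variances).
#' @examples
#' nex_prior_params(0.3)
#' nex_prior_params(c(0.2, 0.5))
#' @export
nex_prior_params <- function(rho) {
  if (length(rho) < 1L || any(!is.finite(rho)) || any(rho <= 0) || any(rho >= 1))
    stop("`rho` must lie strictly inside (0, 1)", call. = FALSE)
  structure(list(m = log(rho / (1 - rho)), v2 = 1 / rho + 1 / (1 - rho)),
            class = "nex_prior")
}

#' Prior configuration for EXNEX and independent analysis models
#'
#' Collects every prior hyperparameter of the EXNEX mixture model and of
#' the independent (NEX-only) analysis model. Defaults follow the standard
#' configuration for a trial with null rate 0.2 and target rate 0.4:
#' exchangeability probabilities `pi = 0.5`, NEX plausible rate
#' `rho = 0.3` (a marginally effective response, between null and target),
#' a `N(logit(q0), 10^2)` prior on the hierarchical mean `mu` and on the
#' independent-model logit rates, and a half-normal(0, 1) prior on the
#' between-basket standard deviation `sigma`.
#'
#' @param q0 Null response rate, in (0, 1).
#' @param q1 Target response rate, in (q0, 1).
#' @param pi Prior probability of exchangeability per basket (scalar or
#'   vector, recycled across baskets).
#' @param rho Plausible NEX response rate per basket (scalar or vector).
#' @param mu_prior_mean,mu_prior_sd Normal prior on the EX common mean
#'   `mu` (logit scale).
#' @param sigma_prior_scale Scale of the half-normal prior on `sigma`.
#' @param indep_prior_mean,indep_prior_sd Normal prior on the logit
#'   response rate in the independent analysis model.
#' @return An object of class `exnex_config`.
#' @examples
#' exnex_config()
#' exnex_config(q0 = 0.15, q1 = 0.35, pi = 0.7)
#' @export
exnex_config <- function(q0 = 0.2, q1 = 0.4, pi = 0.5, rho = 0.3,
                         mu_prior_mean = stats::qlogis(q0),
                         mu_prior_sd = 10,
                         sigma_prior_scale = 1,
                         indep_prior_mean = stats::qlogis(q0),
                         indep_prior_sd = 10) {
  stopifnot(q0 > 0, q0 < 1)
  if (!(q1 > q0 && q1 < 1))
    stop("`q1` must lie in (q0, 1)", call. = FALSE)
  if (any(pi < 0) || any(pi > 1))
    stop("`pi` must lie in [0, 1]", call. = FALSE)
  if (any(rho <= 0) || any(rho >= 1))
    stop("`rho` must lie in (0, 1)", call. = FALSE)
  stopifnot(mu_prior_sd > 0, indep_prior_sd > 0, sigma_prior_scale > 0)
  structure(
    list(q0 = q0, q1 = q1, pi = pi, rho = rho,
         mu_prior_mean = mu_prior_mean, mu_prior_sd = mu_prior_sd,
         sigma_prior_scale = sigma_prior_scale,
         indep_prior_mean = indep_prior_mean,
         indep_prior_sd = indep_prior_sd),
    class = "exnex_config")
}

#' @export
print.exnex_config <- function(x, ...) {
  cat("EXNEX configuration\n")
  cat("  q0 =", x$q0, " q1 =", x$q1, "\n")
  cat("  pi =", paste(x$pi, collapse = ", "),
      " rho =", paste(x$rho, collapse = ", "), "\n")
  cat("  mu ~ N(", signif(x$mu_prior_mean, 4), ", ", x$mu_prior_sd,
      "^2),  sigma ~ half-normal(0, ", x$sigma_prior_scale, ")\n", sep = "")
  cat("  independent model: theta ~ N(", signif(x$indep_prior_mean, 4),
      ", ", x$indep_prior_sd, "^2)\n", sep = "")
  invisible(x)
}

#' MCMC run settings
#'
#' @param n_chains Number of chains run sequentially.
#' @param n_warmup Adaptation/burn-in iterations per chain (discarded).
#' @param n_samples Kept draws per chain (after thinning).
#' @param seed Integer seed, or `NULL` to continue from the current R RNG
#'   state (used by the simulators, which manage their own seed streams).
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param diagnostics If `TRUE`, compute effective sample sizes alongside
#'   split R-hat; simulation loops switch this off for speed.
#' @return An object of class `mcmc_settings`.
#' @examples
#' mcmc_settings(seed = 42)
#' mcmc_settings(n_chains = 1, n_warmup = 500, n_samples = 2500, seed = 1)
#' @export
mcmc_settings <- function(n_chains = 4, n_warmup = 2500, n_samples = 2500,
                          seed = NULL, thin = 1, diagnostics = TRUE) {
  stopifnot(n_chains >= 1, n_warmup >= 0, n_samples >= 1, thin >= 1)
  if (!is.null(seed)) stopifnot(is.finite(seed))
  structure(
    list(n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
         n_samples = as.integer(n_samples),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         thin = as.integer(thin), diagnostics = isTRUE(diagnostics)),
    class = "mcmc_settings")
}

# recycle a scalar-or-vector prior field to length K
recycle_k <- function(x, K, name) {
  if (length(x) == 1L) return(rep(x, K))
  if (length(x) != K)
    stop("`", name, "` must have length 1 or K = ", K, call. = FALSE)
  x
}
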