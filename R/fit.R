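#' Fit the EXNEX mixture model
#'
#' Draws from the joint posterior of the exchangeability-nonexchangeability
#' model for `K` baskets with binomial outcomes. Each basket's logit
#' response rate is, with prior probability `pi[k]`, exchangeable
#' (`theta_k ~ N(mu, sigma^2)`, sharing the hierarchical mean across
#' baskets) and otherwise nonexchangeable with a basket-specific prior
#' `N(m_k, v2_k)` derived from the plausible rate `rho` via
#' [nex_prior_params()]. Sampling is Metropolis-within-Gibbs: the mixture
#' indicators `delta_k` and the common mean `mu` are drawn exactly from
#' their conjugate full conditionals; each `theta_k` uses an independence
#' Metropolis step proposing from the Laplace approximation of its
#' log-concave conditional posterior; `log(sigma)` uses a random-walk
#' step whose scale adapts during warmup.
#'
#' @param data A [basket_data()] object.
#' @param config An [exnex_config()] object.
#' @param mcmc An [mcmc_settings()] object.
#' @return An object of class `exnex_fit` (see Details).
#' @details The returned object contains `theta_draws`, `p_draws`,
#'   `delta_draws` (draws x K matrices), `mu_draws`, `sigma_draws`,
#'   the per-basket posterior exceedance probabilities `exceed_prob`
#'   (`P(p_k > q0 | data)`, the quantity compared against the efficacy
#'   cut-off), `post_mean` and `post_sd` of `p_k`, and `diagnostics`
#'   (split R-hat per basket, effective sample sizes, MH acceptance
#'   rates). Convergence concerns (R-hat > 1.05 or ESS < 400) are recorded
#'   as a warning in `diagnostics$warnings`, never altering the draws.
#' @examples
#' dat <- basket_data(c(7, 4, 5, 9, 3), c(24, 24, 24, 24, 14))
#' fit <- fit_exnex(dat, exnex_config(),
#'                  mcmc_settings(n_chains = 1, n_warmup = 500,
#'                                n_samples = 1000, seed = 1))
#' fit$exceed_prob
#' @export
fit_exnex <- function(data, config = exnex_config(),
                      mcmc = mcmc_settings()) {
  fit_engine(data, config, mcmc, hierarchical = TRUE)
}

#' Fit the independent (NEX-only) analysis model
#'
#' Analyses each basket on its own: `theta_k ~ N(indep_prior_mean,
#' indep_prior_sd^2)` with a binomial likelihood, no cross-basket terms.
#' This is the analysis model used for new baskets under the IND approach
#' and for calibrating their efficacy cut-off.
#'
#' @inheritParams fit_exnex
#' @return An `exnex_fit` object without `delta_draws`, `mu_draws` or
#'   `sigma_draws`.
#' @examples
#' dat <- basket_data(5, 14)
#' fit <- fit_independent(dat, exnex_config(),
#'                        mcmc_settings(n_chains = 1, n_warmup = 500,
#'                                      n_samples = 1000, seed = 1))
#' fit$exceed_prob
#' @export
fit_independent <- function(data, config = exnex_config(),
                            mcmc = mcmc_settings()) {
  fit_engine(data, config, mcmc, hierarchical = FALSE)
}

fit_engine <- function(data, config, mcmc, hierarchical) {
  stopifnot(inherits(data, "basket_data"),
            inherits(config, "exnex_config"),
            inherits(mcmc, "mcmc_settings"))
  K <- data$K
  if (hierarchical) {
    pi_k <- recycle_k(config$pi, K, "pi")
    nex <- nex_prior_params(recycle_k(config$rho, K, "rho"))
    nex_mean <- nex$m
    nex_sd <- sqrt(nex$v2)
  } else {
    pi_k <- rep(0, K)
    nex_mean <- rep(config$indep_prior_mean, K)
    nex_sd <- rep(config$indep_prior_sd, K)
  }
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  raw <- .exnex_mcmc_cpp(
    as.numeric(data$y), as.numeric(data$n), pi_k, nex_mean, nex_sd,
    config$mu_prior_mean, config$mu_prior_sd, config$sigma_prior_scale,
    mcmc$n_chains, mcmc$n_warmup, mcmc$n_samples, mcmc$thin,
    hierarchical)

  p_draws <- stats::plogis(raw$theta)
  colnames(p_draws) <- colnames(raw$theta) <- data$labels
  exceed <- exceedance(p_draws, config$q0)
  diag <- fit_diagnostics(raw, mcmc, K, hierarchical, data$labels)

  structure(
    list(model = if (hierarchical) "exnex" else "independent",
         data = data, config = config, mcmc = mcmc,
         theta_draws = raw$theta, p_draws = p_draws,
         delta_draws = if (hierarchical) raw$delta else NULL,
         mu_draws = if (hierarchical) raw$mu else NULL,
         sigma_draws = if (hierarchical) raw$sigma else NULL,
         exceed_prob = exceed,
         post_mean = colMeans(p_draws),
         post_sd = apply(p_draws, 2, stats::sd),
         diagnostics = diag),
    class = "exnex_fit")
}

#' Posterior exceedance probabilities
#'
#' Per-basket fraction of posterior draws of the response rate strictly
#' above the null rate `q0`; the decision quantity `P(p_k > q0 | data)`.
#'
#' @param p_draws Numeric matrix of response-rate draws (draws x baskets).
#' @param q0 Null response rate.
#' @return Numeric vector of length `ncol(p_draws)`.
#' @examples
#' exceedance(cbind(c(0.1, 0.3, 0.5, 0.15)), q0 = 0.2)  # 0.5
#' @export
exceedance <- function(p_draws, q0) {
  p_draws <- as.matrix(p_draws)
  if (nrow(p_draws) == 0L) stop("empty draw matrix", call. = FALSE)
  colMeans(p_draws > q0)
}

# split R-hat and (optionally) effective sample size per basket
fit_diagnostics <- function(raw, mcmc, K, hierarchical, labels) {
  draws_per_chain <- mcmc$n_samples
  chain_id <- rep(seq_len(mcmc$n_chains), each = draws_per_chain)
  # split each chain in half for R-hat even with a single chain
  half <- rep(rep(1:2, each = ceiling(draws_per_chain / 2),
                  length.out = draws_per_chain), mcmc$n_chains)
  grp <- interaction(chain_id, half, drop = TRUE)

  rhat1 <- function(x) {
    m <- tapply(x, grp, mean); v <- tapply(x, grp, stats::var)
    nn <- length(x) / nlevels(grp)
    W <- mean(v); B <- nn * stats::var(as.numeric(m))
    if (!is.finite(W) || W <= 0) return(1)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }
  rhat <- apply(raw$theta, 2, rhat1)
  ess <- NULL
  if (isTRUE(mcmc$diagnostics)) {
    ess <- apply(raw$theta, 2, ess_geyer)
  }
  warnings <- character()
  if (any(rhat > 1.05))
    warnings <- c(warnings, paste0(
      "split R-hat > 1.05 for: ",
      paste(labels[rhat > 1.05], collapse = ", ")))
  if (!is.null(ess) && any(ess < 400))
    warnings <- c(warnings, paste0(
      "effective sample size < 400 for: ",
      paste(labels[ess < 400], collapse = ", ")))
  list(rhat = stats::setNames(rhat, labels),
       ess = if (is.null(ess)) NULL else stats::setNames(ess, labels),
       accept_theta = raw$accept_theta,
       accept_sigma = if (hierarchical) raw$accept_sigma else NULL,
       warnings = warnings)
}

# Geyer initial monotone positive sequence ESS estimate
ess_geyer <- function(x, max_lag = 200L) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  max_lag <- min(max_lag, n - 2L)
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1]
  s <- 0; prev <- Inf
  for (i in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[i] + rho[i + 1]
    if (pair < 0) break
    pair <- min(pair, prev)  # enforce monotone decrease
    s <- s + pair
    prev <- pair
  }
  n / (1 + 2 * s)
}

#' @export
print.exnex_fit <- function(x, ...) {
  cat("Posterior fit (", x$model, " model), ",
      nrow(x$p_draws), " draws x ", x$data$K, " baskets\n", sep = "")
  out <- data.frame(
    basket = x$data$labels, y = x$data$y, n = x$data$n,
    post_mean = round(x$post_mean, 3), post_sd = round(x$post_sd, 3),
    exceed_prob = round(x$exceed_prob, 4))
  if (!is.null(x$delta_draws))
    out$P_EX <- round(colMeans(x$delta_draws), 3)
  print(out, row.names = FALSE)
  if (length(x$diagnostics$warnings))
    cat("convergence warnings:\n ",
        paste(x$diagnostics$warnings, collapse = "\n  "), "\n")
  invisible(x)
}

#' Write posterior draws to CSV
#'
#' One column per parameter: `theta_<label>` (and `delta_<label>`, `mu`,
#' `sigma` for the EXNEX model), one row per kept draw.
#'
#' @param fit An `exnex_fit` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  stopifnot(inherits(fit, "exnex_fit"))
  out <- as.data.frame(fit$theta_draws)
  names(out) <- paste0("theta_", fit$data$labels)
  if (!is.null(fit$delta_draws)) {
    dd <- as.data.frame(fit$delta_draws)
    names(dd) <- paste0("delta_", fit$data$labels)
    out <- cbind(out, dd, mu = fit$mu_draws, sigma = fit$sigma_draws)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialise posterior summaries to JSON
#'
#' @param fit An `exnex_fit` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
fit_summary_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "exnex_fit"))
  obj <- list(
    model = fit$model,
    baskets = fit$data$labels, y = fit$data$y, n = fit$data$n,
    exceed_prob = unname(fit$exceed_prob),
    post_mean = unname(fit$post_mean), post_sd = unname(fit$post_sd),
    diagnostics = list(rhat = unname(fit$diagnostics$rhat),
                       warnings = fit$diagnostics$warnings))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
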