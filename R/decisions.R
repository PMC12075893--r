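#' Trial structure: existing and new baskets
#'
#' Describes a basket trial in which `K0 = length(n_existing)` baskets
#' opened at the start of the study and `K_new = length(n_new)` baskets
#' were added part-way through (typically with smaller sample sizes).
#' Baskets are indexed existing first, then new.
#'
#' @param n_existing Integer vector of sample sizes for existing baskets.
#' @param n_new Integer vector of sample sizes for new baskets (possibly
#'   empty).
#' @return An object of class `trial_structure`.
#' @examples
#' trial_structure(n_existing = rep(24, 4), n_new = 14)
#' @export
trial_structure <- function(n_existing, n_new = integer()) {
  if (length(n_existing) < 1L)
    stop("at least one existing basket is required", call. = FALSE)
  n_all <- c(n_existing, n_new)
  if (any(n_all < 1) || any(n_all != round(n_all)))
    stop("sample sizes must be positive integers", call. = FALSE)
  structure(
    list(K0 = length(n_existing), K_new = length(n_new),
         n_existing = as.integer(n_existing), n_new = as.integer(n_new)),
    class = "trial_structure")
}

#' Efficacy cut-offs for existing and new baskets
#'
#' Holds the calibrated posterior-probability cut-offs: the treatment is
#' declared effective in basket `k` when `P(p_k > q0 | data)` strictly
#' exceeds the basket's cut-off.
#'
#' @param delta_existing Numeric vector of cut-offs for existing baskets.
#' @param delta_new Numeric vector of cut-offs for new baskets.
#' @param provenance Optional list recording how the cut-offs were
#'   obtained (calibration method, scenarios, weights, replications,
#'   seed).
#' @return An object of class `cutoff_set`.
#' @examples
#' cutoff_set(delta_existing = rep(0.903, 4), delta_new = 0.890)
#' @export
cutoff_set <- function(delta_existing, delta_new = numeric(),
                       provenance = list()) {
  d <- c(delta_existing, delta_new)
  if (length(d) && (any(!is.finite(d)) || any(d <= 0) || any(d >= 1)))
    stop("cut-offs must lie strictly inside (0, 1)", call. = FALSE)
  structure(
    list(delta_existing = as.numeric(delta_existing),
         delta_new = as.numeric(delta_new),
         provenance = provenance),
    class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat("Efficacy cut-offs\n")
  cat("  existing:", paste(round(x$delta_existing, 4), collapse = " "), "\n")
  if (length(x$delta_new))
    cat("  new:     ", paste(round(x$delta_new, 4), collapse = " "), "\n")
  if (length(x$provenance))
    cat("  calibrated by:", x$provenance$method %||% "unknown",
        "(R =", x$provenance$R %||% NA, ", seed =",
        x$provenance$seed %||% NA, ")\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-basket efficacy decisions
#'
#' Compares posterior exceedance probabilities to the calibrated cut-offs
#' with a strict inequality: basket `k` rejects its null hypothesis
#' (treatment declared effective) when `exceed_prob[k] > delta[k]`; ties
#' never reject.
#'
#' @param exceed_prob Numeric vector of `P(p_k > q0 | data)`, existing
#'   baskets first.
#' @param cutoffs A [cutoff_set()] covering all baskets.
#' @return An object of class `basket_decision` with logical vector
#'   `reject`, the probabilities compared (`exceed_prob`) and the
#'   cut-offs used (`delta`).
#' @examples
#' decide(c(0.95, 0.50), cutoff_set(c(0.90, 0.90)))$reject
#' @export
decide <- function(exceed_prob, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  delta <- c(cutoffs$delta_existing, cutoffs$delta_new)
  if (length(exceed_prob) != length(delta))
    stop("`exceed_prob` has length ", length(exceed_prob),
         " but the cut-off set covers ", length(delta), " baskets",
         call. = FALSE)
  if (anyNA(delta) || anyNA(exceed_prob))
    stop("missing cut-off or exceedance probability", call. = FALSE)
  structure(
    list(reject = as.logical(exceed_prob > delta),
         exceed_prob = as.numeric(exceed_prob), delta = delta),
    class = "basket_decision")
}

#' @export
print.basket_decision <- function(x, ...) {
  print(data.frame(exceed_prob = round(x$exceed_prob, 4),
                   cutoff = x$delta, reject = x$reject),
        row.names = FALSE)
  invisible(x)
}

#' Analyse a trial under one of the four basket-addition approaches
#'
#' Runs the analysis model(s) prescribed by the chosen approach and turns
#' the resulting posterior exceedance probabilities into per-basket
#' decisions via [decide()]:
#'
#' * `IND` — EXNEX on the existing baskets only; each new basket analysed
#'   by the independent model (no borrowing involving new baskets).
#' * `UNPL`, `PL1a` — one EXNEX fit on all baskets feeds every decision
#'   (the two approaches differ only in how their cut-offs are
#'   calibrated).
#' * `PL2a` — EXNEX on the existing baskets decides the existing baskets;
#'   a second EXNEX fit on all baskets decides the new baskets. The
#'   all-basket fit's existing-basket posteriors are retained in the
#'   returned fits for transparency but never used for decisions.
#'
#' When `mcmc$seed` is set, fits consume a single RNG stream in a fixed
#' order (existing-basket model first), so approaches sharing an analysis
#' model produce identical draws at the same seed.
#'
#' @param approach One of `"IND"`, `"UNPL"`, `"PL1a"`, `"PL2a"`.
#' @param data A [basket_data()] covering all baskets, existing first.
#' @param structure A [trial_structure()].
#' @param config An [exnex_config()].
#' @param cutoffs A [cutoff_set()] for this approach.
#' @param mcmc An [mcmc_settings()].
#' @return A list of class `trial_analysis` with the `basket_decision`,
#'   the exceedance probabilities, and the underlying fits.
#' @export
analyse_trial <- function(approach, data, structure,
                          config = exnex_config(), cutoffs,
                          mcmc = mcmc_settings()) {
  approach <- match.arg(approach, c("IND", "UNPL", "PL1a", "PL2a"))
  stopifnot(inherits(data, "basket_data"),
            inherits(structure, "trial_structure"))
  K0 <- structure$K0
  K <- K0 + structure$K_new
  if (data$K != K)
    stop("`data` covers ", data$K, " baskets but the structure has ", K,
         call. = FALSE)
  idx_ex <- seq_len(K0)
  idx_new <- setdiff(seq_len(K), idx_ex)

  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  ms <- mcmc
  ms$seed <- NULL

  fits <- list()
  if (approach %in% c("IND", "PL2a") || structure$K_new == 0) {
    fits$existing <- fit_exnex(subset_baskets(data, idx_ex), config, ms)
  }
  if (approach %in% c("UNPL", "PL1a") ||
      (approach == "PL2a" && structure$K_new > 0)) {
    fits$all <- fit_exnex(data, config, ms)
  }
  if (approach == "IND" && structure$K_new > 0) {
    fits$new_independent <-
      fit_independent(subset_baskets(data, idx_new), config, ms)
  }

  exceed <- switch(approach,
    IND = c(fits$existing$exceed_prob,
            if (structure$K_new > 0) fits$new_independent$exceed_prob),
    UNPL = ,
    PL1a = fits$all$exceed_prob,
    PL2a = c(fits$existing$exceed_prob,
             if (structure$K_new > 0) fits$all$exceed_prob[idx_new]))

  base::structure(
    list(approach = approach, decision = decide(exceed, cutoffs),
         exceed_prob = unname(exceed), fits = fits),
    class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat("Approach:", x$approach, "\n")
  print(x$decision)
  invisible(x)
}
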