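#' Load a run configuration from a YAML file
#'
#' Reads and validates a configuration describing a trial: structure
#' (sample sizes), prior settings, MCMC settings, scenario tables, and
#' calibration/study parameters. Unknown keys are rejected by name;
#' missing prior fields receive the standard defaults (`q0 = 0.2`,
#' `q1 = 0.4`, `pi = 0.5`, `rho = 0.3`, normal prior sd 10 on the
#' hierarchical mean).
#'
#' @param path Path to a YAML configuration file.
#' @return A list of class `run_config` with elements `structure`
#'   ([trial_structure()]), `config` ([exnex_config()]), `mcmc`
#'   ([mcmc_settings()]), `scenarios` (list of [scenario()]), `alpha`,
#'   `R`, `reps`, `approaches`, `method` and `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  validate_run_config(raw)
}

validate_run_config <- function(raw) {
  known_top <- c("structure", "priors", "mcmc", "scenarios", "alpha",
                 "R", "reps", "approaches", "method", "seed")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    stop("unknown configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(raw$structure) || is.null(raw$structure$n_existing))
    stop("configuration must name `structure: n_existing`", call. = FALSE)
  unknown_st <- setdiff(names(raw$structure), c("n_existing", "n_new"))
  if (length(unknown_st))
    stop("unknown structure field(s): ",
         paste(unknown_st, collapse = ", "), call. = FALSE)
  st <- trial_structure(raw$structure$n_existing,
                        raw$structure$n_new %||% integer())

  pr <- raw$priors %||% list()
  known_pr <- c("q0", "q1", "pi", "rho", "mu_prior_mean", "mu_prior_sd",
                "sigma_prior_scale", "indep_prior_mean", "indep_prior_sd")
  unknown_pr <- setdiff(names(pr), known_pr)
  if (length(unknown_pr))
    stop("unknown prior field(s): ",
         paste(unknown_pr, collapse = ", "), call. = FALSE)
  q0 <- pr$q0 %||% 0.2
  cfg <- exnex_config(
    q0 = q0, q1 = pr$q1 %||% 0.4,
    pi = pr$pi %||% 0.5, rho = pr$rho %||% 0.3,
    mu_prior_mean = pr$mu_prior_mean %||% stats::qlogis(q0),
    mu_prior_sd = pr$mu_prior_sd %||% 10,
    sigma_prior_scale = pr$sigma_prior_scale %||% 1,
    indep_prior_mean = pr$indep_prior_mean %||% stats::qlogis(q0),
    indep_prior_sd = pr$indep_prior_sd %||% 10)

  mc <- raw$mcmc %||% list()
  known_mc <- c("n_chains", "n_warmup", "n_samples", "thin", "seed")
  unknown_mc <- setdiff(names(mc), known_mc)
  if (length(unknown_mc))
    stop("unknown mcmc field(s): ",
         paste(unknown_mc, collapse = ", "), call. = FALSE)
  mcmc <- mcmc_settings(
    n_chains = mc$n_chains %||% 4, n_warmup = mc$n_warmup %||% 2500,
    n_samples = mc$n_samples %||% 2500, seed = mc$seed,
    thin = mc$thin %||% 1)

  scens <- lapply(raw$scenarios %||% list(), function(s) {
    unknown_s <- setdiff(names(s), c("name", "p", "n", "weight"))
    if (length(unknown_s))
      stop("unknown scenario field(s): ",
           paste(unknown_s, collapse = ", "), call. = FALSE)
    scenario(p = s[["p"]],
             n = s[["n"]] %||% c(st$n_existing, st$n_new),
             weight = s[["weight"]] %||% 1L, name = s[["name"]])
  })

  base::structure(
    list(structure = st, config = cfg, mcmc = mcmc, scenarios = scens,
         alpha = raw$alpha %||% 0.10, R = raw$R %||% 10000L,
         reps = raw$reps %||% 10000L,
         approaches = raw$approaches %||%
           c("IND", "UNPL", "PL1a", "PL2a"),
         method = raw$method %||% "rcap", seed = raw$seed %||% 1L),
    class = "run_config")
}

#' Save a run configuration to YAML
#'
#' Writes a [load_config()]-compatible file; `load_config(save_config(x))`
#' round-trips losslessly.
#'
#' @param cfg A `run_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  raw <- list(
    structure = list(n_existing = cfg$structure$n_existing,
                     n_new = cfg$structure$n_new),
    priors = list(q0 = cfg$config$q0, q1 = cfg$config$q1,
                  pi = cfg$config$pi, rho = cfg$config$rho,
                  mu_prior_mean = cfg$config$mu_prior_mean,
                  mu_prior_sd = cfg$config$mu_prior_sd,
                  sigma_prior_scale = cfg$config$sigma_prior_scale,
                  indep_prior_mean = cfg$config$indep_prior_mean,
                  indep_prior_sd = cfg$config$indep_prior_sd),
    mcmc = list(n_chains = cfg$mcmc$n_chains,
                n_warmup = cfg$mcmc$n_warmup,
                n_samples = cfg$mcmc$n_samples, thin = cfg$mcmc$thin,
                seed = cfg$mcmc$seed),
    scenarios = lapply(cfg$scenarios, function(s)
      list(name = s$name, p = s$p, n = s$n, weight = s$weight)),
    alpha = cfg$alpha, R = cfg$R, reps = cfg$reps,
    approaches = cfg$approaches, method = cfg$method, seed = cfg$seed)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Read observed counts from CSV
#'
#' Expects columns `basket`, `label`, `y`, `n`, `is_new` (existing
#' baskets listed first).
#'
#' @param path CSV file path.
#' @return A list with `data` ([basket_data()]) and `structure`
#'   ([trial_structure()]).
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("basket", "label", "y", "n", "is_new")
  if (!all(need %in% names(df)))
    stop("counts file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  df <- df[order(df$is_new, df$basket), ]
  if (any(diff(df$is_new) < 0))
    stop("existing baskets must precede new baskets", call. = FALSE)
  list(data = basket_data(df$y, df$n, df$label),
       structure = trial_structure(df$n[!as.logical(df$is_new)],
                                   df$n[as.logical(df$is_new)]))
}

#' Write calibrated cut-offs to JSON
#'
#' Records the cut-off values together with full provenance (method,
#' model, scenarios, weights, replications, seed).
#'
#' @param cutoffs A [cutoff_set()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cutoffs <- function(cutoffs, path) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  obj <- list(delta_existing = cutoffs$delta_existing,
              delta_new = cutoffs$delta_new,
              provenance = cutoffs$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read calibrated cut-offs from JSON
#'
#' @param path JSON file written by [write_cutoffs()].
#' @return A [cutoff_set()].
#' @export
read_cutoffs <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cutoff_set(obj$delta_existing, obj$delta_new %||% numeric(),
             provenance = as.list(obj$provenance))
}

#' Built-in design fixtures
#'
#' `"reference"` is the standard 4+1 design this package's simulation
#' studies are built around: four existing baskets of 24 patients, one
#' new basket of 14, null and target rates 0.2/0.4, ten fixed scenarios
#' crossing effective (0.4) and ineffective (0.2) rates, and the four
#' existing-basket scenarios used to calibrate the unplanned-addition
#' approach. `"tiny"` is a 2+1 design with 8/8/6 patients for fast
#' tests.
#'
#' @param name `"reference"` or `"tiny"`.
#' @return A list with `structure`, `config`, `scenarios` (full-trial
#'   scenarios), `unpl_scenarios` (existing-basket scenarios for UNPL
#'   robust calibration), and `rcap_scenarios` (the subset used for
#'   robust calibration of the other approaches).
#' @examples
#' fx <- make_fixture("reference")
#' fx$scenarios[[3]]$p
#' @export
make_fixture <- function(name = c("reference", "tiny")) {
  name <- match.arg(name)
  if (name == "reference") {
    st <- trial_structure(n_existing = rep(24L, 4), n_new = 14L)
    n_all <- c(st$n_existing, st$n_new)
    grid <- list(
      c(0.2, 0.2, 0.2, 0.2, 0.2), c(0.4, 0.2, 0.2, 0.2, 0.2),
      c(0.4, 0.4, 0.4, 0.4, 0.2), c(0.4, 0.4, 0.4, 0.4, 0.4),
      c(0.2, 0.2, 0.2, 0.2, 0.4), c(0.4, 0.2, 0.2, 0.2, 0.4),
      c(0.4, 0.4, 0.2, 0.2, 0.2), c(0.4, 0.4, 0.4, 0.2, 0.2),
      c(0.4, 0.4, 0.2, 0.2, 0.4), c(0.4, 0.4, 0.4, 0.2, 0.4))
    scens <- lapply(seq_along(grid), function(i)
      scenario(grid[[i]], n_all, name = paste0("scenario", i)))
    unpl_grid <- list(
      c(0.2, 0.2, 0.2, 0.2), c(0.4, 0.2, 0.2, 0.2),
      c(0.4, 0.4, 0.2, 0.2), c(0.4, 0.4, 0.4, 0.2))
    unpl <- lapply(seq_along(unpl_grid), function(i)
      scenario(unpl_grid[[i]], st$n_existing,
               name = paste0("unpl_scenario", i)))
    list(structure = st, config = exnex_config(q0 = 0.2, q1 = 0.4),
         scenarios = scens, unpl_scenarios = unpl,
         rcap_scenarios = scens[c(1, 2, 3, 7, 8)])
  } else {
    st <- trial_structure(n_existing = c(8L, 8L), n_new = 6L)
    n_all <- c(st$n_existing, st$n_new)
    grid <- list(c(0.2, 0.2, 0.2), c(0.4, 0.2, 0.2), c(0.4, 0.4, 0.2),
                 c(0.4, 0.4, 0.4), c(0.2, 0.2, 0.4))
    scens <- lapply(seq_along(grid), function(i)
      scenario(grid[[i]], n_all, name = paste0("tiny", i)))
    unpl <- list(scenario(c(0.2, 0.2), st$n_existing, name = "tiny_u1"),
                 scenario(c(0.4, 0.2), st$n_existing, name = "tiny_u2"))
    list(structure = st, config = exnex_config(q0 = 0.2, q1 = 0.4),
         scenarios = scens, unpl_scenarios = unpl,
         rcap_scenarios = scens[1:3])
  }
}
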