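# Shared MCMC settings for tests. `ms_sim` mirrors the reduced per-fit
# settings the simulators use; `ms_precise` buys enough effective draws
# for oracle comparisons at the 2nd-3rd decimal.
ms_sim <- function(seed = NULL)
  mcmc_settings(n_chains = 1, n_warmup = 500, n_samples = 2500,
                seed = seed, diagnostics = FALSE)

ms_fast <- function(seed = NULL)
  mcmc_settings(n_chains = 1, n_warmup = 300, n_samples = 1000,
                seed = seed, diagnostics = FALSE)

ms_precise <- function(seed = 1)
  mcmc_settings(n_chains = 4, n_warmup = 1000, n_samples = 10000,
                seed = seed)
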