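# Reproducible seed substreams for simulation studies.
#
# Every replicate of every scenario gets its own seed derived from the
# master seed, a content hash of the scenario (its true rates and sample
# sizes, not its position in a list) and the replicate index. Deriving
# from content means a scenario listed twice draws identical data in
# matching replicates, which makes integer scenario weights exactly
# equivalent to listing a scenario multiple times. All arithmetic stays
# below 2^53 so the modular products are exact in doubles, and results
# fit in a 32-bit integer for set.seed().

.seed_mod <- 2147483647

scenario_hash <- function(scen) {
  vals <- c(round(scen$p * 1e6), scen$n)
  h <- 0
  for (v in vals) h <- (h * 31 + v) %% .seed_mod
  h
}

substream_seed <- function(master, scen_hash, r) {
  s <- master %% .seed_mod
  s <- (s * 31 + scen_hash) %% .seed_mod
  s <- (s * 48271 + r) %% .seed_mod
  as.integer(s)
}

# clone MCMC settings for use inside a managed seed stream
mcmc_streamed <- function(mcmc) {
  mcmc$seed <- NULL
  mcmc$diagnostics <- FALSE
  mcmc
}
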