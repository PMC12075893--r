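# Example run configuration: the 4+1 reference design.
# Fields omitted under `priors` receive the standard defaults
# (q0 = 0.2, q1 = 0.4, pi = 0.5, rho = 0.3, normal(logit(q0), 10^2)
# priors on the hierarchical mean and independent-model logits,
# half-normal(0, 1) on sigma).
structure:
  n_existing: [24, 24, 24, 24]
  n_new: [14]
priors:
  q0: 0.2
  q1: 0.4
mcmc:
  n_chains: 1
  n_warmup: 500
  n_samples: 2500
scenarios:
- name: global_null
  p: [0.2, 0.2, 0.2, 0.2, 0.2]
- name: one_effective
  p: [0.4, 0.2, 0.2, 0.2, 0.2]
- name: existing_effective
  p: [0.4, 0.4, 0.4, 0.4, 0.2]
  weight: 1
alpha: 0.10
R: 2000
reps: 2000
method: rcap
seed: 1
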