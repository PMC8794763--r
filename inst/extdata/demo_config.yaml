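# Demonstration run: simulate 40 years under the additive-mortality /
# weak-density-dependence AHM model, then benchmark every candidate.
seed: 7
outdir: ahmnull_demo
models: [SaRw, SaRs, ScRw, ScRs, persistence, wetland]
weight_models: [SaRw, SaRs, ScRw, ScRs]
null_id: persistence
standardization: recursive
eval_years: [1991, 2019]
simulate:
  generator: SaRw
  n_years: 40
  N0: 8
  start_year: 1980
  process_sd: 0.05
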