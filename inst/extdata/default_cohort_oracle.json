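{
  "description": "Frozen generating conditions of the default synthetic study cohort",
  "n": 20000,
  "seed": 1,
  "prevalence": 0.3038,
  "bayes_auroc": 0.869047254596995
}
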