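area_source: esv
scc: 1.47
coffee:
  production_rate: 0.84
  price_usd_t: 4685
  cost_fraction: 0.13
delta: 0.5
sensitivity_mode: per_class
seed: 1
quiet: true
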