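name: Inclusion of bioinformatic development costs
investments:
- label: pipeline_development
  total_cost: 1695000.0
  currency: NOK
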