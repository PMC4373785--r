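{
  "description": "Net cytosolic ATP production: mitochondrial ATP synthase minus mitochondrial NDP kinase, minus the ATP-consuming kinases of upper glycolysis, plus the ATP-producing payoff-phase kinases (phosphoglycerate kinase carries a negative flux when producing ATP).",
  "sense": "maximize",
  "coefficients": {
    "R_ATPS4m": 1, "R_NDPK1m": -1, "R_HEX1": -1,
    "R_PFK": -1, "R_PGK": -1, "R_PYK": 1
  }
}
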