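{
  "description": "Measured cerebral exchange fluxes for healthy elderly human subjects at rest, whole-brain scale (brain mass 1.4 kg). Positive = uptake into brain, negative = release. Units mmol/min.",
  "exchange_fluxes": {
    "R_GLCt1r":   {"metabolite": "glucose",  "value": 0.284,  "sd": 0.058},
    "R_L_LACt2r": {"metabolite": "lactate",  "value": -0.013, "sd": 0.032},
    "R_PYRt2r":   {"metabolite": "pyruvate", "value": -0.003, "sd": 0.004}
  },
  "ppp_fraction": 0.069,
  "gaba_fraction": 0.32,
  "brain_mass_kg": 1.4,
  "g6pd_reaction": "R_G6PDH2r",
  "gad_reaction": "R_GLUDC",
  "glycerol3p_dehydrogenase_reaction": "R_G3PD2m"
}
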