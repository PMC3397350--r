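{
  "comment": "Chinese DRI reference values for zinc in adults (2000 edition) plus IZiNCG mixed-diet absorption fractions and absorbed-zinc inadequacy cutoffs. The insufficiency cutoff is insufficiency_fraction x RNI. RNI strata split males at 49/50 years while UL strata split at 50/51 years; the one-year mismatch is in the source reference values and is preserved.",
  "rni_mg_day": {
    "male": [
      {"age_min": 20, "age_max": 49, "value": 15.0},
      {"age_min": 50, "age_max": null, "value": 11.5}
    ],
    "female": [
      {"age_min": 20, "age_max": null, "value": 11.5}
    ]
  },
  "insufficiency_fraction": {"numerator": 2, "denominator": 3},
  "ul_mg_day": {
    "male": [
      {"age_min": 20, "age_max": 50, "value": 45.0},
      {"age_min": 51, "age_max": null, "value": 37.0}
    ],
    "female": [
      {"age_min": 20, "age_max": null, "value": 37.0}
    ]
  },
  "absorption_fraction": {"male": 0.26, "female": 0.34},
  "absorbed_inadequacy_mg_day": {"male": 2.69, "female": 1.86}
}
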