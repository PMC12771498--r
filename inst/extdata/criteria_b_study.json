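{
  "label": "B",
  "description": "Current-clinical-practice benchmark: clinical goals with two bounds relaxed to the pooled verification-anatomy quartiles of the nine-patient study cohort (PTVpsv D98% and rectum V36Gy).",
  "rows": [
    {"structure": "ctv_psv", "metric_kind": "v_dose_rel", "level": 40,    "direction": "target_coverage", "optimal": 95,    "mandatory": 90,    "marginal": 85,   "can_be_unacceptable": true},
    {"structure": "ptv_psv", "metric_kind": "v_dose_rel", "level": 36.25, "direction": "target_coverage", "optimal": 95,    "mandatory": 90,    "marginal": 85,   "can_be_unacceptable": true},
    {"structure": "ptv_psv", "metric_kind": "d_percent",  "level": 98,    "direction": "target_coverage", "optimal": 34.4,  "mandatory": 32.38, "marginal": null, "can_be_unacceptable": true},
    {"structure": "bladder", "metric_kind": "v_dose_abs", "level": 37,    "direction": "oar_sparing",     "optimal": 5,     "mandatory": 10,    "marginal": null, "can_be_unacceptable": true},
    {"structure": "bladder", "metric_kind": "v_dose_rel", "level": 18.1,  "direction": "oar_sparing",     "optimal": null,  "mandatory": 40,    "marginal": null, "can_be_unacceptable": true},
    {"structure": "rectum",  "metric_kind": "v_dose_abs", "level": 36,    "direction": "oar_sparing",     "optimal": 1,     "mandatory": 3.04,  "marginal": null, "can_be_unacceptable": true},
    {"structure": "rectum",  "metric_kind": "v_dose_rel", "level": 29,    "direction": "oar_sparing",     "optimal": null,  "mandatory": 20,    "marginal": null, "can_be_unacceptable": true},
    {"structure": "rectum",  "metric_kind": "v_dose_rel", "level": 18.1,  "direction": "oar_sparing",     "optimal": null,  "mandatory": 50,    "marginal": null, "can_be_unacceptable": true},
    {"structure": "bowel",   "metric_kind": "v_dose_abs", "level": 30,    "direction": "oar_sparing",     "optimal": null,  "mandatory": 1,     "marginal": null, "can_be_unacceptable": true},
    {"structure": "bowel",   "metric_kind": "v_dose_abs", "level": 18.1,  "direction": "oar_sparing",     "optimal": null,  "mandatory": 5,     "marginal": null, "can_be_unacceptable": true},
    {"structure": "urethra", "metric_kind": "v_dose_rel", "level": 42,    "direction": "oar_sparing",     "optimal": 50,    "mandatory": 100,   "marginal": null, "can_be_unacceptable": false}
  ]
}
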