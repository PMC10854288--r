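{
  "schema": "qdg-reference/1",
  "n_subjects": 42,
  "constants": {
    "amp_max_mm": 12.5,
    "reference_age_years": 60,
    "mobility_scale": 14,
    "mobility_n": 6,
    "pa_transform_A": 3.2,
    "pa_transform_k": 0.495,
    "pa_z_transition": 10,
    "pa_z_cap": 20,
    "rt_A": 4,
    "rt_k": 0.05,
    "rt_b": -1,
    "low_tremor_pct_threshold": 10
  },
  "metrics": {
    "press_amplitude_mm": {
      "mean": 8.65383893500201,
      "sd": 0.138456194240316,
      "direction": "lower_worse",
      "age_slope": 0,
      "threshold": 8.56013155197386
    },
    "press_amplitude_cv": {
      "mean": 0.028911229576073,
      "sd": 0.0072576138621053,
      "direction": "higher_worse",
      "age_slope": 0.000143262395510557,
      "threshold": 0.034219073521205
    },
    "isi_s": {
      "mean": 0.503315748480264,
      "sd": 0.0183147989551671,
      "direction": "higher_worse",
      "age_slope": 0,
      "threshold": 0.515587014411027
    },
    "isi_cv": {
      "mean": 0.0508998517413622,
      "sd": 0.0120844718638237,
      "direction": "higher_worse",
      "age_slope": 0,
      "threshold": 0.0598481932825528
    },
    "press_speed_mm_s": {
      "mean": 82.955702521765,
      "sd": 3.57065539345169,
      "direction": "lower_worse",
      "age_slope": -0.255667714355399,
      "threshold": 80.0273463767996
    },
    "release_slope_mm_s": {
      "mean": 82.6941307958705,
      "sd": 3.84691660360771,
      "direction": "lower_worse",
      "age_slope": -0.184233518735534,
      "threshold": 80.3121238787402
    },
    "taps_per_minute": {
      "mean": 235.285714285714,
      "sd": 8.47171970990575,
      "direction": "lower_worse",
      "age_slope": 0,
      "threshold": 230
    },
    "mobility_score": {
      "mean": 94.3285465673111,
      "sd": 3.61558648029648,
      "direction": "lower_worse",
      "age_slope": 0,
      "threshold": 91.9552969107262
    }
  }
}
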