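{
  "comment": "Reference oxytetracycline cattle population model, single-run estimates. Volumes mL/kg, clearances mL/kg/h, rate constants 1/h, lag h, bioavailabilities on the logit scale. Omega blocks are labelled lower triangles of the absorption and disposition variance-covariance matrices.",
  "theta": {
    "tvV1": 126,
    "tvV2": 914,
    "tvV3": 2564,
    "tvCl": 62.67,
    "tvCld2": 485,
    "tvCld3": 19.96,
    "tvKa1": 0.214,
    "tvKa2": 0.0441,
    "tvTlag": 14.96,
    "tvF1": 1.281,
    "tvFrapid": 0.757
  },
  "covariate_effects": {
    "V1": 0.320,
    "V2": 0.159,
    "V3": 0.358,
    "Cl": 0.548,
    "Cld2": 0.190,
    "Cld3": 0.293
  },
  "omega": {
    "absorption": {
      "labels": ["nKa1", "nKa2", "nF1", "nTlag", "nFrapid"],
      "lower": [
        [0.080095],
        [0.103949, 0.19011],
        [-0.095537, -0.138489, 0.331033],
        [-0.02741, -0.02635, 0.068231, 0.040549],
        [0.02069, 0.038294, -0.05192, -0.01144, 0.015948]
      ]
    },
    "disposition": {
      "labels": ["nV1", "nV2", "nV3", "nCl", "nCl2", "nCl3"],
      "lower": [
        [0.527444],
        [-0.07716, 0.031032],
        [-0.07185, 0.02222, 0.107616],
        [0.055107, -0.00525, 0.018945, 0.039763],
        [0.010349, 0.013185, 0.041094, 0.016754, 0.047794],
        [0.080094, 0.009562, 0.055244, 0.045213, 0.029476, 0.19877]
      ]
    }
  },
  "residual": {
    "cv_prop": 0.182,
    "sd_add": 0.0069
  }
}
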