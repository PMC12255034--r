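{
  "comment": "Fixture configuration for accessibility-coupling calibration: the target G4-ATAC Pearson correlation and the simulation cohort geometries used to calibrate beta_a and to evaluate the calibrated generator.",
  "target_r": 0.309,
  "calibration_cohort": { "n_chrom": 2, "n_genes": 800 },
  "n_calibration_seeds": 5,
  "calibration_tol": 0.015,
  "evaluation_cohort": { "n_chrom": 4, "n_genes": 7000 }
}
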