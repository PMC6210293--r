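# Full default configuration for the wristcal pipeline.
# Omitted fields fall back to package defaults; activity profiles default
# to default_activity_profiles() unless overridden under generator.activities.
generator:
  n_children: 167
  epochs_per_activity: 60      # 5-min bouts of 5-s epochs
  p_stand: 0.05                # chance a seated session is contaminated
  child_effect_sd: 0.3         # log-scale SD of the per-child effect
  handedness_right: 0.9
  seed: 20180926
bootstrap:
  B: 100
  alpha: 0.05
  seed: 20180926
calibration:
  k: 10
  calibration_fraction: 0.5988 # 100 of 167 children
  seed: 20180926
  signals: [axis1, axis2, axis3, vm]
  mode: cv                     # or: repeats
  eval: out_of_fold            # or: in_fold
  pooled_sedentary: false
  validation_B: 200
output_dir: wristcal_output
log_level: info
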