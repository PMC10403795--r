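target_baseline_median: 10000.0
between_log_sd: 0.22
within_log_sd: 0.25
self_efficacy_mean: 72.0
self_efficacy_sd: 10.0
responsiveness: 2200.0
effort_margin: 700.0
drive_slope: 0.6
efficacy_scale: 10.0
conf_slope: 3.0
conf_noise_sd: 4.0
mastery_gain: 2.0
failure_loss: 4.0
wear_prob: 0.97
recording_failure_prob: 0.01
dropout_hazard: 0.0015
bp_response: 2.0
weight_response: 1.0
bp_record_prob: 0.95
glucose_user_prob: 0.3
seasonal_amplitude: 0.0
gap_days: 5.0
stage_probs:
  precontemplation: 0.1
  contemplation: 0.15
  preparation: 0.5
  action: 0.1
  maintenance: 0.15
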