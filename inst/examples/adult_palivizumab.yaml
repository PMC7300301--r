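# Adult palivizumab reference run: calibrate the FcRn affinity so that the
# simulated adult NCA clearance matches the adult population-PK value of
# 198 ml/day, then simulate a single 15 mg/kg IV dose.
drug:
  name: palivizumab
  calibrate_to: 198        # ml/day
individual:
  age_y: 35
  sex: male
regimen:
  dose_mg_kg: 15
analysis:
  model_kind: pbpk
  growth: false
  obs_days: 150
  dt: 0.5
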