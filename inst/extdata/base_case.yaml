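# Base-case run configuration. Every key is optional; omitted keys fall back
# to the packaged defaults, so an empty file reproduces the base case.
settings:
  cycle_length_days: 21
  horizon_years: 5
  discount_rate: 0.03
  start_age: 65
  wtp_thresholds: [100000, 150000]
  half_cycle_correction: true
scenario:
  mode: extrapolate      # extrapolate | pessimistic | optimistic
  switch_time: 17        # months of trial follow-up
  anchor: 0.278          # pessimistic 3-year survival anchor (0.238 selectable)
  anchor_time: 36
analysis:
  dsa: false
  psa: false
  psa_iterations: 10000
  two_way: false
  price_thresholds: false
seed: 1
output_dir: hccea-output
# parameters:            # any base value can be overridden by name, e.g.
#   hr_os: 0.58
#   cost_atezo: 9419.16
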