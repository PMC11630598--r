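# Run configuration for the lifetime cost-utility model.
discount_rate: 0.03          # annual, applied to costs and outcomes
wtp_threshold: 160000        # baht per QALY
start_age: 40                # cohort entry age, years
max_age: 100                 # horizon cap, years
cycle_length: 1              # years; only supported value
rr_mortality: 2.0            # mortality rate ratio, obesity with T2DM vs general population
half_cycle: false            # half-cycle correction off by default
occupancy_floor: 1.0e-5      # stop propagation when living mass falls below this
psa_draws: 1000
seed: 4243
visit_profile:               # annualization of per-visit non-medical items
  op_t2dm: 4                 # outpatient visits/year, non-remission
  op_remission: 2            # outpatient visits/year, remission
  ip: 0.1                    # inpatient admissions/year, all living states
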