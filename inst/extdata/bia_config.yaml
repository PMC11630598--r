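# Budget impact configuration: national eligible-population cascade and
# 5-year projection settings. Printed headline counts are carried as
# constants; the cascade also reports the values re-derived from the rates.
total_population_18_65: 45094408
bmi30_population: 6359953
class_shares_pct: [4.0, 0.8, 0.1]   # obesity class I / II / III, % of population
bmi_cut: 32.5                       # eligibility BMI threshold
bmi_eligible_population: 3764102    # BMI >= cut, aged 18-65 (published count)
t2dm_share: 0.111                   # share of obesity with T2DM
eligible_t2dm_population: 417865    # BMI >= cut with T2DM (published count)
at_risk_population: 3346237         # BMI >= cut without T2DM
incidence_8yr_men: 0.2252           # 8-year cumulative T2DM incidence, men
incidence_8yr_women: 0.1803         # 8-year cumulative T2DM incidence, women
male_share_at_risk: 0.5             # sex split of the at-risk population (assumption)
annual_incident_cases: 90744        # published annual incident count
horizon_years: 5
uptake: [1, 0, 0, 0, 0]             # fraction of the prevalent stock operated per year
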