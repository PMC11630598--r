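# Model input parameters: annual transition probabilities, costs (2023 baht),
# and utility weights, each with mean and standard error and the distribution
# family used for probabilistic resampling (beta for probabilities/utilities,
# gamma for costs). cycle_scope marks year-since-baseline indexed entries.
name,family,mean,se,role,arm_scope,cycle_scope
p_remission_nonbs,beta,0.0156,0.0047,transition,nonsurgery,
p_remission_bs_y1,beta,0.4333,0.13,transition,surgery,1
p_remission_bs_y2,beta,0.2941,0.0882,transition,surgery,2
p_remission_bs_y3,beta,0.0833,0.025,transition,surgery,3
p_remission_bs_y4plus,beta,0.0156,0.0047,transition,surgery,4+
p_relapse_nonbs,beta,0.0708,0.0212,transition,nonsurgery,
p_relapse_bs,beta,0.0107,0.0032,transition,surgery,
p_t2dm_mi,beta,0.0008,0.0002,transition,both,
p_t2dm_stroke,beta,0.0031,0.0009,transition,both,
p_t2dm_chf,beta,0.002,0.0006,transition,both,
p_t2dm_ckd,beta,0.0066,0.002,transition,both,
p_remission_mi,beta,0.0007,0.0002,transition,both,
p_remission_stroke,beta,0.0027,0.0008,transition,both,
p_remission_chf,beta,0.002,0.0006,transition,both,
p_remission_ckd,beta,0.0049,0.0015,transition,both,
p_death_mi,beta,0.032,0.0096,transition,both,
p_death_stroke,beta,0.0494,0.0148,transition,both,
p_death_chf,beta,0.325,0.0975,transition,both,
p_death_ckd,beta,0.1098,0.0329,transition,both,
c_treat_t2dm_nonbs,gamma,30504.77,1066.81,cost_medical,nonsurgery,
c_treat_remission_nonbs,gamma,15437.65,5893.15,cost_medical,nonsurgery,
c_surgery,gamma,279899.62,6865.92,cost_medical,surgery,0
c_treat_t2dm_bs_y1,gamma,36536.72,7987.91,cost_medical,surgery,1
c_treat_t2dm_bs_y2,gamma,30114.01,8517.57,cost_medical,surgery,2
c_treat_t2dm_bs_y3plus,gamma,30589.87,8298.79,cost_medical,surgery,3+
c_treat_remission_bs_y1,gamma,16518.51,2483.20,cost_medical,surgery,1
c_treat_remission_bs_y2,gamma,16941.94,1299.82,cost_medical,surgery,2
c_treat_remission_bs_y3plus,gamma,9085.91,1200.82,cost_medical,surgery,3+
c_mi_y1,gamma,119212.12,47059.54,cost_medical,both,
c_mi_later,gamma,28612.87,41451.42,cost_medical,both,
c_stroke,gamma,46501.62,12464.44,cost_medical,both,
c_chf,gamma,59300.76,10902.97,cost_medical,both,
c_ckd,gamma,53085.23,18647.41,cost_medical,both,
c_accommodation_y1,gamma,5598.86,1571.74,cost_nonmedical,both,1
c_renovation_y1,gamma,1159.09,734.09,cost_nonmedical,both,1
c_op_travel,gamma,766.36,88.54,cost_nonmedical,both,
c_op_food,gamma,275.45,57.23,cost_nonmedical,both,
c_op_hotel,gamma,73.86,32.63,cost_nonmedical,both,
c_op_informal,gamma,81.85,25.23,cost_nonmedical,both,
c_ip_travel,gamma,1062.50,849.36,cost_nonmedical,both,
c_ip_food,gamma,425,265.75,cost_nonmedical,both,
c_ip_informal,gamma,4242.86,2034.44,cost_nonmedical,both,
c_informal_t2dm,gamma,12396.90,8649.82,cost_nonmedical,both,
c_hiring_t2dm,gamma,22307.69,9962.56,cost_nonmedical,both,
c_informal_remission,gamma,4933.46,4933.46,cost_nonmedical,both,
c_hiring_remission,gamma,14448.98,5813.21,cost_nonmedical,both,
c_outside_remission,gamma,2348.98,422.75,cost_nonmedical,both,
c_outside_t2dm_nonbs,gamma,1396.77,547.32,cost_nonmedical,nonsurgery,
c_outside_t2dm_bs,gamma,10645.88,1781.32,cost_nonmedical,surgery,
c_nonmed_mi,gamma,51785.00,1822.00,cost_nonmedical,both,
c_nonmed_stroke,gamma,63159.45,18947.84,cost_nonmedical,both,
c_nonmed_chf,gamma,33942.00,6912.00,cost_nonmedical,both,
c_nonmed_ckd,gamma,168863.00,50658.90,cost_nonmedical,both,
u_t2dm,beta,0.83,0.02,utility,both,
u_remission,beta,0.97,0.01,utility,both,
u_mi,beta,0.79,0.01,utility,both,
u_stroke,beta,0.6,0.02,utility,both,
u_chf,beta,0.75,0.03,utility,both,
u_ckd,beta,0.7,0.03,utility,both,
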