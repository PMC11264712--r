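lambda_wtp: 30000.0
annual_incidence: 2450.0
horizon_years: 10.0
P: 24500.0
I: 0.0
c_pair: 1650.0
fixed_cost_pre: 90216.0
fixed_cost_during: 204581.0
fixed_cost_post: 336042.0
delta_years: 1.0
recruit_rate: 74.0
tau: 74
t_max: 124
trial_days: 611.0
mu0: 0.0
sigma_x: 7615.0
n0: 2.0
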