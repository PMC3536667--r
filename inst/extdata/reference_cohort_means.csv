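parameter,fpacq_mean,fpacq_sd,swd_mean,swd_sd
pal,1.76,0.23,1.62,0.25
total_ee,296.49,38.39,271.40,41.09
moderate_pa,2.47,3.02,7.67,7.14
vigorous_pa,2.34,2.68,0.68,1.23
sedentary,37.85,16.65,62.86,12.61
job_time,37.77,10.12,33.08,11.40
job_ee,89.12,26.70,61.39,25.63
sports_time,2.58,3.44,3.12,3.45
sports_ee,19.04,29.51,14.86,17.08
screen_time,14.65,7.85,14.70,9.02
household_time,10.20,6.33,15.03,9.36
household_ee,30.14,19.71,36.78,24.03
active_transport_time,3.81,3.87,2.45,2.61
active_transport_ee,15.24,15.49,8.21,9.61
motorized_time,6.33,4.03,8.99,4.31
motorized_ee,9.50,6.04,17.67,9.03
eating_time,5.62,2.42,9.42,3.62
eating_ee,10.12,4.35,15.86,6.55
sleeping_time,48.90,7.01,56.19,9.39
sleeping_ee,44.01,6.31,53.88,7.96
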