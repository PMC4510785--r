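variable,routine,intensive
n,511,513
age_mean,60.1,61.1
age_sd,7.5,7.2
female,0.407,0.366
caucasian,0.867,0.918
smoker,0.180,0.177
bmi_mean,33.0,33.1
bmi_sd,5.9,5.6
chol_mean,5.5,5.3
chol_sd,1.2,1.1
hdl_mean,1.2,1.2
hdl_sd,0.3,0.4
sbp_mean,143.1,142.0
sbp_sd,19.4,20.1
hba1c_mean,7.3,7.3
hba1c_sd,1.7,1.7
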