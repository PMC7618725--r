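metric,group,mean,sd,n
age_years,HC,61.76,16.42,33
age_years,ALS,61.02,12.65,42
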