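variable,group,n_pairs,bias,sd,upper,lower
spo2,overall,4521,-1.28,NA,4.399,-6.960
dbp,overall,4480,-1.399,NA,17.713,-20.517
sbp,overall,4480,-1.536,NA,22.708,-25.780
hr,overall,4480,0.566,NA,3.680,-2.548
spo2,covid,2363,-1.260,2.890,4.402,-6.923
spo2,non_covid,2158,-1.304,2.913,4.407,-7.015
dbp,covid,2344,-0.968,9.637,17.921,-19.858
dbp,non_covid,2136,-1.873,9.876,17.489,-21.230
sbp,covid,2344,-1.172,12.613,23.549,-25.894
sbp,non_covid,2136,-1.934,12.109,21.800,-25.669
hr,covid,2344,-0.493,1.595,3.621,-2.637
hr,non_covid,2136,-0.646,1.579,3.741,-2.448
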