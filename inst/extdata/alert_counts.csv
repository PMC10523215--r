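label,n_events,n_volunteers
dbp_maxima,7,3
dbp_minima,0,0
sbp_maxima,4,2
sbp_minima,0,0
low_oxygen_saturation,1200,67
low_heart_rate,21,5
total_reported,1312,69
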