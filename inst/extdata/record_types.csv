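type,n
continuous_heart_bpm,10510351
heart_bpm,289749
oxygen_saturation,25212
blood_pressure,16123
sleep,12410
sleep_intensity,375951
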