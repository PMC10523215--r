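stage,n
recruited,122
no_show_interview,17
not_eligible_interview,10
dropped_after_inclusion,12
dropped_after_start,3
retained,80
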