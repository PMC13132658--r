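target_id,decoy_id,tm_ref,sigma,bp_disruption
synth_out,decoy_01,0.627810037504445,0.2,0
synth_out,decoy_02,0.16109658664496,0.9,0
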