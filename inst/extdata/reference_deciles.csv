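group,agp_ref,crp_ref,source
PSC,0.59,0.1,external
WRA,0.54,0.16,external
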