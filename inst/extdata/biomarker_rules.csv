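biomarker,group,use_agp,use_crp,conditional,expected_sign
ferritin,PSC,TRUE,TRUE,FALSE,positive
stfr,PSC,TRUE,FALSE,FALSE,positive
retinol,PSC,TRUE,TRUE,FALSE,negative
rbp,PSC,TRUE,TRUE,FALSE,negative
zinc,PSC,TRUE,TRUE,TRUE,negative
serum_folate,PSC,FALSE,FALSE,FALSE,none
rbc_folate,PSC,FALSE,FALSE,FALSE,none
b12,PSC,FALSE,FALSE,FALSE,none
ferritin,WRA,TRUE,TRUE,FALSE,positive
stfr,WRA,TRUE,FALSE,FALSE,positive
retinol,WRA,TRUE,TRUE,FALSE,negative
rbp,WRA,TRUE,TRUE,FALSE,negative
zinc,WRA,FALSE,FALSE,FALSE,none
serum_folate,WRA,FALSE,FALSE,FALSE,none
rbc_folate,WRA,FALSE,FALSE,FALSE,none
b12,WRA,FALSE,FALSE,FALSE,none
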