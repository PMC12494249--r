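patient_id,age,sex,bmi
P1,70,male,25
P2,55,female,12
P3,63,male,NA
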