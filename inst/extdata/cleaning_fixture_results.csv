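patient_id,date,value,unit
P1,2015-01-01,50,mmol/mol
P1,2015-02-01,52.3,mmol/mol
P1,2015-03-01,49.8,mmol/mol
P1,2015-04-01,55,mmol/mol
P1,2015-04-01,51,mmol/mol
P2,2015-01-10,7.7,mmol/mol
P2,2015-02-10,6.5,percent
P2,2015-03-10,210,mmol/mol
P2,2015-04-10,48,mmol/mol
P3,2015-01-05,52.0,mmol/mol
P3,2015-02-05,52.0,mmol/mol
P3,2015-03-05,52.0,mmol/mol
P3,2015-04-05,52.0,mmol/mol
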