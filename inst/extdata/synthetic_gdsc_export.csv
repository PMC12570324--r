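SCAN_ID,POSITION,DRUG_ID,CONC,INHIBITION,TAG
900001,1,,,-1.2,NC
900001,2,,,2.1,NC
900001,25,,,98.7,PC
900001,26,,,101.3,PC
900001,51,D1001,0.01,4.5,DRUG
900001,52,D1001,0.1,21.0,DRUG
900001,53,D1001,1,64.2,DRUG
900001,54,D1001,10,88.9,DRUG
900001,75,D1002,0.1,1.9,DRUG
900001,76,D1002,1,12.4,DRUG
900001,77,D1002,10,47.8,DRUG
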