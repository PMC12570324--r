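barcode,row_name,col_name,broad_id,dose,inhibition,well_type
BRD-PLATE-01,A,1,,,0.8,negcon
BRD-PLATE-01,B,1,,,-2.3,negcon
BRD-PLATE-01,A,24,,,97.5,poscon
BRD-PLATE-01,B,24,,,102.0,poscon
BRD-PLATE-01,C,3,BRD-K0001,0.00061,3.1,treatment
BRD-PLATE-01,C,4,BRD-K0001,0.0024,8.8,treatment
BRD-PLATE-01,C,5,BRD-K0001,0.0098,24.6,treatment
BRD-PLATE-01,C,6,BRD-K0001,0.039,55.1,treatment
BRD-PLATE-01,C,7,BRD-K0001,0.156,79.0,treatment
BRD-PLATE-01,C,8,BRD-K0001,0.625,90.3,treatment
BRD-PLATE-01,C,9,BRD-K0001,2.5,95.8,treatment
BRD-PLATE-01,C,10,BRD-K0001,10,97.2,treatment
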