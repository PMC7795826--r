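patient_id,n_biopsies_taken,n_positive,height_cm,weight_kg
P01,12,7,165,83.6
P02,8,2,157,78.5
P03,6,2,163,57.2
P04,6,1,163,76.3
P05,5,1,158,70.5
P06,4,1,154,60.5
P07,3,1,160,62.1
P08,13,0,163,66.4
P09,13,0,155,59
P10,12,0,161,73.8
P11,11,0,161,57.3
P12,10,0,162,62
P13,9,0,157,52
P14,8,0,160,53.4
P15,8,0,163,79.3
P16,7,0,163,63.8
P17,7,0,168,63.7
P18,7,0,162,73.5
P19,7,0,164,56.3
P20,6,0,159,44.5
P21,6,0,166,60.6
P22,5,0,168,50.1
P23,5,0,170,55.5
P24,4,0,168,35.5
P25,3,0,168,52.9
P26,3,0,152,60.1
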