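name,plasmid_type,species,pcn,pcn_sd,cost,cost_sd,reference
pB1006,ColE1,Haemophilus influenzae RdKW20,10.530,1.112,0.021,0.012,Santos-Lopez et al. 2017
pB1005,ColE1,Haemophilus influenzae RdKW20,20.450,2.590,0.05,0.013,Santos-Lopez et al. 2017
pB1000,ColE1,Haemophilus influenzae RdKW20,25.020,1.920,0.054,0.002,Santos-Lopez et al. 2017
pNI105,,Pseudomonas aeruginosa,18.000,2.400,0.132,0.025,San Millan et al. 2014
2-uM,,Saccharomyces cerevisiae,52.000,0.000,0.0884,0.00416,Harrison et al. 2015
pNUK73,,Pseudomonas aeruginosa,11.030,1.890,0.214,0.008,San Millan et al. 2014
pBGT,ColE1,Escherichia coli,19.120,1.560,0.057,0.013,San Millan et al. 2016
pBGT R164S,ColE1,Escherichia coli,21.100,0.850,0.057,0.003,San Millan et al. 2016
pBGT G54U,ColE1,Escherichia coli,44.500,3.810,0.207,0.019,San Millan et al. 2016
pBGT G55U,ColE1,Escherichia coli,88.930,15.650,0.443,0.116,San Millan et al. 2016
pBGT R164S G54U,ColE1,Escherichia coli,52.300,2.190,0.238,0.016,San Millan et al. 2016
pBGT R164S G55U,ColE1,Escherichia coli,127.290,4.580,0.491,0.082,San Millan et al. 2016
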