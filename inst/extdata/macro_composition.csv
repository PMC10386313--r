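parameter,group,mean,sd,n,letter
pH,January,5.07,0.12,15,ab
pH,April,5.10,0.12,15,a
pH,June,5.01,0.14,15,b
Moisture,January,31.86,1.43,15,a
Moisture,April,31.51,0.97,15,a
Moisture,June,31.57,1.05,15,a
Fat/DM,January,49.54,1.31,15,b
Fat/DM,April,47.60,1.40,15,c
Fat/DM,June,50.58,1.28,15,a
Protein/DM,January,36.65,0.94,15,b
Protein/DM,April,38.22,1.12,15,a
Protein/DM,June,35.43,1.10,15,c
Fat/Protein,January,1.35,0.05,15,b
Fat/Protein,April,1.25,0.05,15,c
Fat/Protein,June,1.43,0.06,15,a
NaCl,January,4.48,0.88,15,c
NaCl,April,4.59,0.83,15,b
NaCl,June,5.02,0.98,15,a
Ash,January,7.20,0.83,15,a
Ash,April,7.48,0.81,15,a
Ash,June,7.57,0.95,15,a
SN/TN,January,14.95,2.25,15,a
SN/TN,April,14.28,3.11,15,a
SN/TN,June,13.99,2.07,15,a
SN-TCA/TN,January,21.21,2.13,15,a
SN-TCA/TN,April,11.92,2.36,15,a
SN-TCA/TN,June,11.22,2.24,15,a
SN-PTA/TN,January,9.71,2.51,15,a
SN-PTA/TN,April,9.27,1.79,15,a
SN-PTA/TN,June,9.08,1.89,15,a
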