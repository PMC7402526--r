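compound,cell_type,ec50_nM,emax_total
abemaciclib,HSC,111.199,0.91
abemaciclib,MPP,46.123,0.002
abemaciclib,GMP,37.326,1.034
abemaciclib,GranP,33.181,0.002
abemaciclib,Gran,38.891,0.002
abemaciclib,MonoP,42.516,0.002
abemaciclib,Mono,46.187,0.231
abemaciclib,Neut,66.213,0.235
abemaciclib,ErythI,29.184,1.024
abemaciclib,ErythII,45.082,0.033
abemaciclib,MK,486.023,0.068
abemaciclib,LymP,36.507,0.002
abemaciclib,B,69.229,0.649
dinaciclib,HSC,70.67,1.031
dinaciclib,MPP,16.681,0.694
dinaciclib,GMP,49.137,0.001
dinaciclib,GranP,548.688,0
dinaciclib,Gran,167.897,2.01
dinaciclib,MonoP,31.343,0
dinaciclib,Mono,28.381,0.482
dinaciclib,Neut,14.199,0.281
dinaciclib,ErythI,25.77,1.115
dinaciclib,ErythII,32.781,0.071
dinaciclib,MK,23.213,0.331
dinaciclib,LymP,25.655,1.149
dinaciclib,B,41.555,0.774
docetaxel,HSC,33.732,1.3
docetaxel,MPP,4.706,2.014
docetaxel,GMP,102.942,0
docetaxel,GranP,127.836,0
docetaxel,Gran,7.907,2.762
docetaxel,MonoP,7.885,1.459
docetaxel,Mono,9.03,0.198
docetaxel,Neut,13.699,0.232
docetaxel,ErythI,8.136,1.726
docetaxel,ErythII,6.299,0.016
docetaxel,MK,7.789,0.126
docetaxel,LymP,17.633,0.002
docetaxel,B,10.386,1.019
paclitaxel,HSC,62.3,1.188
paclitaxel,MPP,42.378,0.002
paclitaxel,GMP,28.21,0.001
paclitaxel,GranP,98.209,0
paclitaxel,Gran,15.772,2.36
paclitaxel,MonoP,24.767,1.556
paclitaxel,Mono,30.004,0.258
paclitaxel,Neut,25.092,0.214
paclitaxel,ErythI,15.356,1.466
paclitaxel,ErythII,20.18,0.071
paclitaxel,MK,51.732,0.259
paclitaxel,LymP,11.696,0.002
paclitaxel,B,36.695,0.914
palbociclib,HSC,165.661,0.776
palbociclib,MPP,354.142,0
palbociclib,GMP,54.617,0.884
palbociclib,GranP,0.105,0.047
palbociclib,Gran,20.732,0
palbociclib,MonoP,33.48,0
palbociclib,Mono,39.336,0.142
palbociclib,Neut,74.956,0.184
palbociclib,ErythI,42.506,0
palbociclib,ErythII,99.537,0.118
palbociclib,MK,758.847,0.074
palbociclib,LymP,23.977,0
palbociclib,B,90.551,0.499
pictilisib,HSC,289.334,0.486
pictilisib,MPP,368.7,0
pictilisib,GMP,1.406,0.071
pictilisib,GranP,93.047,0.605
pictilisib,Gran,0.167,0.232
pictilisib,MonoP,116.627,1.399
pictilisib,Mono,1023.971,0.039
pictilisib,Neut,131.773,0.165
pictilisib,ErythI,190.664,0
pictilisib,ErythII,190.999,0.136
pictilisib,MK,1070.272,0.123
pictilisib,LymP,3.805,0
pictilisib,B,91.304,0.514
ribociclib,HSC,372.722,0.489
ribociclib,MPP,700.61,0
ribociclib,GMP,140.666,0.76
ribociclib,GranP,21.418,0.064
ribociclib,Gran,22.176,0
ribociclib,MonoP,75.973,0
ribociclib,Mono,180.253,0.195
ribociclib,Neut,177.785,0.139
ribociclib,ErythI,88.607,0.001
ribociclib,ErythII,222.347,0.108
ribociclib,MK,2044.762,0.048
ribociclib,LymP,12.339,0
ribociclib,B,35.828,0.305
thalidomide,HSC,189.555,0
thalidomide,MPP,718.402,0
thalidomide,GMP,176.993,0
thalidomide,GranP,128.605,0
thalidomide,Gran,36.708,0
thalidomide,MonoP,305.042,0
thalidomide,Mono,694.357,0
thalidomide,Neut,0.302,0.011
thalidomide,ErythI,424.67,0
thalidomide,ErythII,1379.963,0
thalidomide,MK,321.784,0
thalidomide,LymP,20.077,0
thalidomide,B,130.058,0.002
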