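channel,theta,phi
Fp1,72.9089,108.8623
Fpz,72,90
Fp2,72.9089,71.1377
AF3,61.6062,131.9256
AFz,54,90
AF4,61.6062,48.0744
F7,75.5225,169.1877
F5,61.6062,156.875
F3,49.1176,141.0266
F1,39.6981,118.9332
Fz,36,90
F2,39.6981,61.0668
F4,49.1176,38.9734
F6,61.6062,23.125
F8,75.5225,10.8123
FT7,72.9089,174.2664
FC5,56.0122,167.3461
FC3,39.6981,156.9587
FC1,25.2428,136.437
FCz,18,90
FC2,25.2428,43.563
FC4,39.6981,23.0413
FC6,56.0122,12.6539
FT8,72.9089,5.7336
T7,72,180
C5,54,180
C3,36,180
C1,18,180
Cz,0,0
C2,18,0
C4,36,0
C6,54,0
T8,72,0
TP7,72.9089,-174.2664
CP5,56.0122,-167.3461
CP3,39.6981,-156.9587
CP1,25.2428,-136.437
CPz,18,-90
CP2,25.2428,-43.563
CP4,39.6981,-23.0413
CP6,56.0122,-12.6539
TP8,72.9089,-5.7336
P7,75.5225,-169.1877
P5,61.6062,-156.875
P3,49.1176,-141.0266
P1,39.6981,-118.9332
Pz,36,-90
P2,39.6981,-61.0668
P4,49.1176,-38.9734
P6,61.6062,-23.125
P8,75.5225,-10.8123
PO3,61.6062,-131.9256
POz,54,-90
PO4,61.6062,-48.0744
O1,72.9089,-108.8623
Oz,72,-90
O2,72.9089,-71.1377
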