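aa,hydropathy,mol_weight,vdw_volume,polarity,isoelectric_point,net_charge,hbond_donor,hbond_acceptor,flexibility,helix_propensity,sheet_propensity,max_asa,aromaticity
A,1.8,89.09,67,8.1,6.00,0,0,0,0.357,1.42,0.83,129,0
C,2.5,121.16,86,5.5,5.07,0,1,0,0.346,0.70,1.19,167,0
D,-3.5,133.10,91,13.0,2.77,-1,1,4,0.511,1.01,0.54,193,0
E,-3.5,147.13,109,12.3,3.22,-1,1,4,0.497,1.51,0.37,223,0
F,2.8,165.19,135,5.2,5.48,0,0,0,0.314,1.13,1.38,240,1
G,-0.4,75.07,48,9.0,5.97,0,0,0,0.544,0.57,0.75,104,0
H,-3.2,155.16,118,10.4,7.59,0.1,1,1,0.323,1.00,0.87,224,0.5
I,4.5,131.17,124,5.2,6.02,0,0,0,0.462,1.08,1.60,197,0
K,-3.9,146.19,135,11.3,9.74,1,2,0,0.466,1.16,0.74,236,0
L,3.8,131.17,124,4.9,5.98,0,0,0,0.365,1.21,1.30,201,0
M,1.9,149.21,124,5.7,5.74,0,0,0,0.295,1.45,1.05,224,0
N,-3.5,132.12,96,11.6,5.41,0,2,2,0.463,0.67,0.89,195,0
P,-1.6,115.13,90,8.0,6.30,0,0,0,0.509,0.57,0.55,159,0
Q,-3.5,146.15,114,10.5,5.65,0,2,2,0.493,1.11,1.10,225,0
R,-4.5,174.20,148,10.5,10.76,1,5,0,0.529,0.98,0.93,274,0
S,-0.8,105.09,73,9.2,5.68,0,1,2,0.507,0.77,0.75,155,0
T,-0.7,119.12,93,8.6,5.60,0,1,2,0.444,0.83,1.19,172,0
V,4.2,117.15,105,5.9,5.96,0,0,0,0.386,1.06,1.70,174,0
W,-0.9,204.23,163,5.4,5.89,0,1,0,0.305,1.08,1.37,285,1
Y,-1.3,181.19,141,6.2,5.66,0,1,1,0.420,0.69,1.47,263,1
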