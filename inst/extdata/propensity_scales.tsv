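residue	flexibility	hydrophilicity	surface_exposure	polarity	beta_turn	accessibility
A	1.041	2.1	0.3	8.1	0.66	0.815
C	0.846	1.4	0.9	5.5	1.19	0.394
D	1.033	10.0	-0.6	13.0	1.46	1.283
E	1.094	7.8	-0.7	12.3	0.74	1.445
F	0.930	-9.2	0.5	5.2	0.60	0.695
G	1.142	5.7	0.3	9.0	1.56	0.714
H	0.982	2.1	-0.1	10.4	0.95	1.180
I	1.002	-8.0	0.7	5.2	0.47	0.603
K	1.093	5.7	-1.8	11.3	1.01	1.545
L	0.967	-9.2	0.5	4.9	0.59	0.603
M	0.947	-4.2	0.4	5.7	0.60	0.714
N	1.117	7.0	-0.5	11.6	1.56	1.296
P	1.055	2.1	-0.3	8.0	1.52	1.236
Q	1.165	6.0	-0.7	10.5	0.98	1.348
R	1.038	4.2	-1.4	10.5	0.95	1.475
S	1.169	6.5	-0.1	9.2	1.43	1.115
T	1.073	5.2	-0.2	8.6	0.96	1.184
V	0.982	-3.7	0.6	5.9	0.50	0.606
W	0.925	-10.0	0.3	5.4	0.96	0.808
Y	0.961	-1.9	-0.4	6.2	1.14	1.089
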