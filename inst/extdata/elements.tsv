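symbol	mono	avg
H	1.00782503207	1.008
C	12.0	12.011
N	14.0030740048	14.007
O	15.9949146196	15.999
S	31.97207100	32.06
P	30.97376163	30.973761998
Na	22.9897692809	22.98976928
K	38.96370668	39.0983
Cl	34.96885268	35.45
Ca	39.96259098	40.078
Mg	23.98504170	24.305
Fe	55.93493630	55.845
Zn	63.92914220	65.38
Cu	62.92959750	63.546
Se	79.91652130	78.971
F	18.99840322	18.998403162
I	126.90447300	126.90447
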