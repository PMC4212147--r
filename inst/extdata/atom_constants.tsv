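element	mass	vdw_volume	sanderson_en	polarizability
H	1.008	0.3517	0.9439	0.379
B	10.811	1.4406	0.8285	1.7216
C	12.011	1	1	1
N	14.007	0.758	1.1631	0.625
O	15.999	0.7148	1.3307	0.4557
F	18.998	0.6466	1.4567	0.3165
Na	22.99	2.3808	0.3041	13.6989
Si	28.086	1.885	0.7786	3.0568
P	30.974	1.1871	0.9159	2.0625
S	32.06	1.1871	1.0768	1.6477
Cl	35.453	1.0909	1.2655	1.2386
Br	79.904	1.2887	1.1723	1.733
I	126.904	1.58	1.0117	3.0398
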