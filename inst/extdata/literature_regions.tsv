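region	hemisphere	x	y	z	source
STS	right	50	-40	12	Grosbras et al. 2005
PMV	left	-50	5	22	Mayka et al. 2006
IPL	left	-32	-40	52	Blangero et al. 2009
VIP	right	38	-44	46	Bremmer et al. 2001
FEF	right	31	-2	47	Paus 1996
SPL	right	23	-64	44	Nickel and Seitz 2005
mIPS	right	18	-60	54	Blangero et al. 2009
M1	left	-37	-21	58	Mayka et al. 2006
S1	left	-40	-24	50	Mayka et al. 2006
AG	right	36.3	-70.5	42.6	Vesia et al. 2010
SMA	left	-2	-7	55	Mayka et al. 2006
SPOC	right	9.5	-80.6	44.2	Vesia et al. 2010
PMd	left	-30	-4	58	Mayka et al. 2006
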