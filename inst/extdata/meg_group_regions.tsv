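region	hemisphere	mean_x	mean_y	mean_z	sd_x	sd_y	sd_z
STS	left	-45.2	-57.1	14.7	4.2	2.6	3.7
PMV	left	-49.6	4.8	21.3	3.0	3.0	3.8
IPL	left	-42.5	-35.3	49.2	3.9	4.9	3.4
VIP	left	-37.1	-40.2	44.4	2.4	3.5	2.3
FEF	left	-28.4	-1.2	43.4	4.4	4.2	3.6
SPL	left	-23.2	-54.3	46.0	3.8	3.8	6.7
mIPS	left	-22.0	-61.3	39.5	2.0	3.5	4.6
M1	left	-35.1	-23.4	53.8	4.4	4.4	3.8
S1	left	-39.5	-24.5	48.0	3.7	2.9	3.5
AG	left	-35.3	-60.8	35.4	4.9	7.5	4.0
SMA	left	-4.4	-9.2	51.8	4.6	6.5	2.9
SPOC	left	-9.0	-71.0	36.7	6.7	4.8	5.8
PMd	left	-30.0	-1.4	47.0	8.3	5.4	8.2
STS	right	48.5	-40.5	11.7	2.9	4.9	4.6
PMV	right	48.9	8.4	21.2	4.2	3.8	3.3
IPL	right	40.9	-40.6	39.3	3.7	4.6	4.6
VIP	right	37.0	-44.0	47.3	3.9	2.6	5.1
FEF	right	31.2	-2.2	44.7	5.1	5.3	6.6
SPL	right	26.9	-55.1	49.3	4.8	2.2	2.3
mIPS	right	23.3	-61.8	40.4	4.1	4.5	5.6
M1	right	36.7	-23.0	52.4	3.3	5.0	4.2
S1	right	39.2	-25.9	40.2	3.8	4.7	25.3
AG	right	32.2	-69.5	34.7	4.2	4.7	2.6
SMA	right	2.7	-7.0	48.9	3.3	4.9	3.6
SPOC	right	9.6	-77.0	34.4	8.1	3.1	4.8
PMd	right	28.6	-5.3	49.9	3.9	8.0	6.2
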