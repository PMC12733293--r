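compound	ic50_ng_ml	ic50_sd	cr_percent	cr_sd	censored
GAT	0.27	0.04	100	NA	0
CIN	NA	NA	NA	NA	1
CIP	9.85	0.31	2.74	0.08	0
CLI	NA	NA	NA	NA	1
DAN	NA	NA	NA	NA	1
DIF	NA	NA	NA	NA	1
ENO	NA	NA	NA	NA	1
ENR	NA	NA	NA	NA	1
FLU	NA	NA	NA	NA	1
GAR	NA	NA	NA	NA	1
LOM	1.54	0.13	17.5	0.5	0
MAR	NA	NA	NA	NA	1
MOX	NA	NA	NA	NA	1
NAD	NA	NA	NA	NA	1
OFL	NA	NA	NA	NA	1
NAL	NA	NA	NA	NA	1
ORB	NA	NA	NA	NA	1
OXO	NA	NA	NA	NA	1
PAZ	NA	NA	NA	NA	1
PEF	NA	NA	NA	NA	1
PIP	NA	NA	NA	NA	1
RUF	NA	NA	NA	NA	1
SAR	11.2	4.0	2.41	0.9	0
S-OFL	NA	NA	NA	NA	1
SPA	NA	NA	NA	NA	1
TOS	NA	NA	NA	NA	1
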