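hapten	label	ring_sum
S-GAT	cross_reactive	10189
S-LOM	cross_reactive	15231
R-LOM	cross_reactive	11178
CIP	cross_reactive	4169
SAR	cross_reactive	5028
CIN	non_cross_reactive	450
CLI	non_cross_reactive	735
CLI*	non_cross_reactive	851
DAN	non_cross_reactive	3252
DAN**	non_cross_reactive	2167
DIF	non_cross_reactive	7905
ENO	non_cross_reactive	3232
ENR	non_cross_reactive	462
FLU	non_cross_reactive	456
FLU*	non_cross_reactive	0
GAR	non_cross_reactive	710
MAR	non_cross_reactive	462
MAR**	non_cross_reactive	462
MOX	non_cross_reactive	1362
NAD	non_cross_reactive	1062
NAD*	non_cross_reactive	882
NAL	non_cross_reactive	0
R-OFL	non_cross_reactive	3227
S-OFL	non_cross_reactive	211
ORB	non_cross_reactive	11033
OXO	non_cross_reactive	0
PAZ	non_cross_reactive	1840
PEF	non_cross_reactive	460
PIP	non_cross_reactive	3339
RUF	non_cross_reactive	644
SPA	non_cross_reactive	858
TOS	non_cross_reactive	628
TOS*	non_cross_reactive	462
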