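hapten	label	lowest_energy_kcal	mean_energy_kcal
S-GAT	cross_reactive	-10.02	-9.98
S-LOM	cross_reactive	-9.13	-9.06
R-LOM	cross_reactive	-9.13	-9.04
CIP	cross_reactive	-8.53	-8.5
SAR	cross_reactive	-9.67	-9.62
CIN	non_cross_reactive	-6.1	-6.08
CLI	non_cross_reactive	-7.84	-7.79
CLI*	non_cross_reactive	-8.28	-7.88
DAN	non_cross_reactive	-8.65	-8.63
DAN**	non_cross_reactive	-7.52	-7.47
DIF	non_cross_reactive	-8.63	-8.27
ENO	non_cross_reactive	-8.24	-8.12
ENR	non_cross_reactive	-8.13	-8
FLU	non_cross_reactive	-6.68	-6.68
FLU*	non_cross_reactive	-6.49	-6.49
GAR	non_cross_reactive	-9.05	-8.83
MAR	non_cross_reactive	-8.09	-8.05
MAR**	non_cross_reactive	-8.01	-7.88
MOX	non_cross_reactive	-8.43	-8.31
NAD	non_cross_reactive	-7.79	-7.47
NAD*	non_cross_reactive	-7.64	-7.41
NAL	non_cross_reactive	-5.59	-5.58
R-OFL	non_cross_reactive	-7.97	-7.93
S-OFL	non_cross_reactive	-8.04	-8.01
ORB	non_cross_reactive	-8.54	-8.32
OXO	non_cross_reactive	-6.17	-6.17
PAZ	non_cross_reactive	-8.59	-8.5
PEF	non_cross_reactive	-7.29	-7.24
PIP	non_cross_reactive	-8.23	-8.17
RUF	non_cross_reactive	-7.45	-7.41
SPA	non_cross_reactive	-7.94	-7.87
TOS	non_cross_reactive	-8.71	-8.58
TOS*	non_cross_reactive	-9.2	-9.15
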