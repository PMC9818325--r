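gene	class	carriers
PMS2	established	4
NBN	established	4
FH	established	0
RET	established	2
DMBT1	candidate	2
RAD50	candidate	3
ATRIP	candidate	3
BLM	candidate	7
ERCC2	candidate	8
LIG3	candidate	1
MSH3	candidate	6
SLX4	candidate	2
AXIN1	candidate	0
ERCC5	candidate	0
ERCC6	candidate	0
EXO1	candidate	2
FANCA	candidate	7
FANCD2	candidate	0
FANCG	candidate	2
HOXB13	candidate	4
MCPH1	candidate	10
MDC1	candidate	0
MLH3	candidate	1
MMP8	candidate	5
NHEJ1	candidate	0
PIK3CG	candidate	0
PMS1	candidate	2
RAD1	candidate	0
RECQL5	candidate	6
SBDS	candidate	13
SETX	candidate	10
SMARCA4	candidate	0
TLR2	candidate	1
TLR4	candidate	2
XRCC1	candidate	7
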