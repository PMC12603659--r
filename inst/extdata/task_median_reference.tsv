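task_id	median_within	median_between
ISU	0.17	0.18
CLRSHP	0.25	0.18
NUMLIST	0.17	0.1
SRC	0.36	0.23
NUMLET	0.32	0.17
EF	0.34	0.19
SIMON	0.16	0
COUNTSW	0.58	0.42
GRIDUP	0.34	0.17
O-ATTN	0.57	0.39
GNG	0.12	-0.07
STERN	0.51	0.29
RANDNUM	0.38	0.15
STROOP	0.57	0.31
C-ATTN	0.59	0.32
NUM-STR	0.49	0.21
ARR-STR	0.51	0.22
FLANKER	0.43	0.13
SPA-WM	0.37	0.04
COM-STR	0.53	0.19
N-BACK	0.65	0.26
ITEMREC	0.42	0.02
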