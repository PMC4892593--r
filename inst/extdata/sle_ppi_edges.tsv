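gene_a	gene_b	evidence	score
IFI6	STAT1	textmining	0.5
IFI6	PLSCR1	textmining	0.5
IFI6	IFI44L	coexpression	0.6
IFI6	IFI27	coexpression	0.6
IFI6	OAS2	textmining	0.5
IFI6	OAS1	textmining	0.5
STAT1	EIF2AK2	textmining	0.6
EIF2AK2	OAS1	coexpression	0.6
OAS1	OAS2	experimental	0.9
OAS1	IFI44L	coexpression	0.6
OAS2	IFI27	coexpression	0.6
STAT1	IRF5	textmining	0.5
STAT1	ITGAX	textmining	0.5
STAT1	ITGAM	textmining	0.5
STAT1	BLK	experimental	0.8
STAT1	ETS1	textmining	0.5
STAT1	CDKN1B	textmining	0.5
STAT1	GHR	textmining	0.5
STAT1	TYRO3	experimental	0.8
STAT1	SOCS6	experimental	0.8
OAS1	SEC61G	experimental	0.8
OAS2	SEC61G	experimental	0.8
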