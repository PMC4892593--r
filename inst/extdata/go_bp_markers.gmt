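GO:0009615	response to virus	PLSCR1	EIF2AK2	STAT1
GO:0006955	immune response	IFI44L	OAS1	OAS2	IFI6
GO:0006401	RNA catabolic process	RNASE2	OAS2
GO:0043281	regulation of caspase activity	STAT1	IFI6
GO:0052548	regulation of endopeptidase activity	STAT1	IFI6
GO:0052547	regulation of peptidase activity	STAT1	IFI6
GO:0006915	apoptosis	EIF2AK2	STAT1	IFI6
GO:0012501	programmed cell death	EIF2AK2	STAT1	IFI6
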