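KEGG::EGF/MAPK	epidermal growth factor / MAP kinase signaling	CSK	PRKA	PRKX	SRC	ERK1	ERK5	RAF1	MEK1
KEGG::WNT	WNT signaling	PRKA	CCND1	CSNK1D	CTNNB1	LEF1	APC	AXIN1
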