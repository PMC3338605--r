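a	b	source	evidence_type	pubmed_ids
GJA1	CSK	HPRD	small_scale_physical	9535909
GJA1	PRKA	BioGRID	small_scale_physical	11790773
GJA1	PRKX	STRING	high_throughput_physical
GJA1	SRC	HPRD	small_scale_physical	9535909
GJA1	ERK1	BioGRID	small_scale_physical	9660788
GJA1	ERK5	STRING	high_throughput_physical
GJA1	CCND1	BioGRID	small_scale_physical
GJA1	CSNK1D	HPRD	small_scale_physical	12270943
GJA1	CTNNB1	BioGRID	small_scale_physical	10839829
GJA1	LEF1	STRING	high_throughput_physical
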