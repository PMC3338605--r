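a	b	source	evidence_type	pubmed_ids
C27F2.4	BAR-1	WI8	high_throughput_physical	14704431
C27F2.4	CLK-2	WI8	high_throughput_physical	14704431
C27F2.4	RHA-2	WI8	high_throughput_physical	14704431
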