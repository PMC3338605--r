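SignaLink::WNT	WNT signaling	BAR-1	POP-1	MOM-2	LIN-17
SignaLink::EGF/MAPK	epidermal growth factor / MAP kinase signaling	BAR-1	LET-60	SEM-5	LIN-3
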