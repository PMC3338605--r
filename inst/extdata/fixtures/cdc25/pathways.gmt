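SignaLink::EGF/MAPK	epidermal growth factor / MAP kinase signaling	LET-60	SEM-5	LIN-3	LET-23	MPK-1
SignaLink::IGF	insulin / insulin-like growth factor signaling	DAF-2	AGE-1	DAF-16
SignaLink::Notch	Notch signaling	GLP-1	LAG-1	LIN-12
SignaLink::TGF	transforming growth factor beta signaling	SMA-6	DBL-1	SMA-4
SignaLink::WNT	WNT signaling	POP-1	BAR-1	MOM-2	LIN-17
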