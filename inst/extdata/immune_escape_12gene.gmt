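immune_escape	12-gene immune escape signature	TIMP1	PXDN	COL15A1	OLFML2B	COL5A2	DLX5	SOX11	KLHDC8A	UNC5A	ADAMTS14	MMP11	FN1
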