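type	value
gene	EGFR
gene	KRAS
gene	BRAF
gene	ERBB2
gene	MET
gene	ALK
gene	RET
gene	ROS1
gene	TP53
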