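source	target	sign
PLC	PIP2	+
PLC	PIP3	+
PIP3	PIP2	+
PIP3	AKT	+
ERK	AKT	+
PKC	JNK	+
PKC	P38	+
PKC	PKA	+
PKC	RAF	+
PKC	MEK	+
PKA	JNK	+
PKA	P38	+
PKA	RAF	+
PKA	MEK	+
PKA	ERK	+
PKA	AKT	+
RAF	MEK	+
MEK	ERK	+
PLC	PKC	+
PIP2	PKC	+
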