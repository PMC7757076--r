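pattern	class
LINE	LINE
SINE	SINE
LTR	LTR
DNA	DNA
RC	DNA
Satellite	Satellite
Simple_repeat	SimpleRepeat
Low_complexity	LowComplexity
rRNA	rRNA
snRNA	Other
scRNA	Other
srpRNA	Other
tRNA	Other
Retroposon	Other
Unknown	Unknown
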