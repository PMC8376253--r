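class_number	genotype_label	E8.5	E10.5	E12.5	E18.5	Postnatal
12	Naa10 -/Y ; Naa12 -/-	0	0	0	0	0
11	Naa10 -/Y ; Naa12 +/-	40	35	10	10	0
6	Naa10 +/- ; Naa12 -/-	40	33	0	0	0
5	Naa10 +/- ; Naa12 +/-	100	100	100	100	35
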