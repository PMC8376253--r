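label	dead	total	description
naa10_null_male_preP3	29	38	Naa10 -/Y pups found dead before P3 (het dam x WT sire matings)
maternal_effect_day1	37	127	pups dead in first 24 h, Naa10 -/- dam x WT sire mating
maternal_effect_3day	46	127	pups dead in first three days, Naa10 -/- dam x WT sire mating
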