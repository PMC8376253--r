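# The two matings with embryonic genotype data: compound-heterozygous dams
# crossed to Naa12-het or Naa12-null sires.
loci:
  - name: Naa10
    linkage: x_linked
  - name: Naa12
    linkage: autosomal
crosses:
  - cross_id: chet_dam_x_het_sire
    dam:  {Naa10: "+/-", Naa12: "+/-"}
    sire: {Naa10: "+/Y", Naa12: "+/-"}
  - cross_id: chet_dam_x_null_sire
    dam:  {Naa10: "+/-", Naa12: "+/-"}
    sire: {Naa10: "+/Y", Naa12: "-/-"}
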