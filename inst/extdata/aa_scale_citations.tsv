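scale	citation_tag
kyte_doolittle	Kyte & Doolittle (1982) J Mol Biol 157:105-132, hydropathy
hopp_woods	Hopp & Woods (1981) PNAS 78:3824-3828, hydrophilicity
eisenberg	Eisenberg, Schwarz, Komaromy & Wall (1984) J Mol Biol 179:125-142, normalized consensus hydrophobicity
bulkiness_zimmerman	Zimmerman, Eliezer & Simha (1968) J Theor Biol 21:170-201, bulkiness
flexibility_bhaskaran	Bhaskaran & Ponnuswamy (1988) Int J Pept Protein Res 32:241-255, average flexibility
janin_accessible	Janin (1979) Nature 277:491-492, molar fraction (%) of 3220 accessible residues
janin_buried	Janin (1979) Nature 277:491-492, molar fraction (%) of 2001 buried residues
zhao_london_tm	Zhao & London (2006) Protein Sci 15:1987-2001, transmembrane tendency
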