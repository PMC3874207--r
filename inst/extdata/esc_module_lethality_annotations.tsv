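# Published embryonic-lethality knockout phenotypes (Mouse Genome
# Database terms) of proteins in a combined embryonic stem cell TRM of
# 77 proteins. Transcribed from the published per-gene table.
# MP:0011096 = complete embryonic lethality between implantation and
# somite formation; MP:0011106 = partial embryonic lethality between
# implantation and somite formation.
# module_size=77
term	gene	symbol
MP:0011096	93760	Arid1a
MP:0011106	15251	Hif1a
MP:0011096	18519	Kat2b
MP:0011096	17187	Max
MP:0011096	71950	Nanog
MP:0011096	18999	Pou5f1
MP:0011096	99377	Sall4
MP:0011096	20466	Sin3a
MP:0011096	20674	Sox2
MP:0011096	20848	Stat3
MP:0011096	22059	Trp53
MP:0011096	93765	Ube2n
MP:0011096	226442	Zfp281
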