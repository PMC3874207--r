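term	name
MP:0011096	complete embryonic lethality between implantation and somite formation
MP:0011106	partial embryonic lethality between implantation and somite formation
MP:0001606	impaired hematopoiesis
MP:0002123	abnormal hematopoiesis
MP:0002401	abnormal lymphopoiesis
MP:0002429	abnormal blood cell morphology/development
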