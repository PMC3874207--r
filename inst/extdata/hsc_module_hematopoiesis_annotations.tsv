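# Published hematopoietic knockout phenotypes (Mouse Genome Database
# terms) of proteins in a combined hematopoietic stem cell TRM of 96
# proteins. Transcribed from the published per-gene table, which pools
# MP:0001606 (impaired hematopoiesis) and MP:0002123 (abnormal
# hematopoiesis) under "hematopoiesis"; both ids are assigned to those
# rows here. MP:0002401 = abnormal lymphopoiesis; MP:0002429 = abnormal
# blood cell morphology/development.
# module_size=96
term	gene	symbol
MP:0001606	12400	Cbfb
MP:0002123	12400	Cbfb
MP:0001606	12914	Crebbp
MP:0002123	12914	Crebbp
MP:0002401	23871	Ets1
MP:0001606	14011	Etv6
MP:0002123	14011	Etv6
MP:0002401	14011	Etv6
MP:0001606	14247	Fli1
MP:0002123	14247	Fli1
MP:0002401	14281	Fos
MP:0001606	14460	Gata1
MP:0002123	14460	Gata1
MP:0001606	14461	Gata2
MP:0002123	14461	Gata2
MP:0002429	14461	Gata2
MP:0002429	14582	Gfi1b
MP:0001606	15412	Hoxb4
MP:0002123	15412	Hoxb4
MP:0001606	15414	Hoxb6
MP:0002123	15414	Hoxb6
MP:0001606	16452	Jak2
MP:0002123	16452	Jak2
MP:0002429	16909	Lmo2
MP:0001606	17268	Meis1
MP:0002123	17268	Meis1
MP:0001606	18514	Pbx1
MP:0002123	18514	Pbx1
MP:0001606	12394	Runx1
MP:0002123	12394	Runx1
MP:0001606	12393	Runx2
MP:0002123	12393	Runx2
MP:0001606	20375	Sfpi1
MP:0002123	20375	Sfpi1
MP:0002429	20375	Sfpi1
MP:0002429	20586	Smarca4
MP:0002429	20587	Smarcb1
MP:0001606	21349	Tal1
MP:0002123	21349	Tal1
MP:0002401	21423	Tcf3
MP:0002429	21423	Tcf3
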