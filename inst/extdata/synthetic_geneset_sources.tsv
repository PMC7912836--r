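source	symbol	accession	name
uniprot_cilia	GENE0001	Q00001	synthetic cilia protein 1
uniprot_cilia	GENE0002	Q00002	synthetic cilia protein 2
uniprot_cilia	GENE0003	Q00003	synthetic cilia protein 3
uniprot_cilia	GENE0004	Q00004	synthetic cilia protein 4
uniprot_cilia	GENE0005	Q00005	synthetic cilia protein 5
uniprot_cilia	GENE0006	Q00006	synthetic cilia protein 6
uniprot_cilia	GENE0007	Q00007	synthetic cilia protein 7
uniprot_cilia	GENE0008	Q00008	synthetic cilia protein 8
uniprot_cilia	GENE0010	Q00010	synthetic cilia protein 10
uniprot_cilia	GENE0011	Q00011	synthetic cilia protein 11
uniprot_ciliopathy	GENE0001	Q00001	synthetic cilia protein 1
uniprot_ciliopathy	GENE0002	Q00002	synthetic cilia protein 2
uniprot_ciliopathy	GENE0005	Q00005	synthetic cilia protein 5
uniprot_ciliopathy	GENE0009	Q00009	synthetic cilia protein 9
uniprot_ciliopathy	GENE0012	Q00012	synthetic cilia protein 12
genomes100k	GENE0002	Q00002	synthetic cilia protein 2
centrosomedb	GENE0002	Q00002	synthetic cilia protein 2
centrosomedb	GENE0011	Q00011	synthetic cilia protein 11
cildb	GENE0001	Q00001	synthetic cilia protein 1
cildb	GENE0003	Q00003	synthetic cilia protein 3
cildb	GENE0005	Q00005	synthetic cilia protein 5
cildb	GENE0011	Q00011	synthetic cilia protein 11
syscilia	GENE0001	Q00001	synthetic cilia protein 1
syscilia	GENE0003	Q00003	synthetic cilia protein 3
syscilia	GENE0006	Q00006	synthetic cilia protein 6
syscilia	GENE0010	Q00010	synthetic cilia protein 10
ciliacarta	GENE0004	Q00004	synthetic cilia protein 4
ciliacarta	GENE0008	Q00008	synthetic cilia protein 8
ciliacarta	GENE0010	Q00010	synthetic cilia protein 10
ciliacarta	GENE0011	Q00011	synthetic cilia protein 11
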