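taxon	genome_size_bp	gene_count	lifestyle	centrioles
T012	25653601	6513	parasite	1
T008	62968018	3735	parasite	1
T002	16952689	7029	parasite	0
T001	106058317	12800	nonparasite	1
T006	608635519	17650	nonparasite	0
T003	78391116	3300	parasite	0
T005	11762607	3026	parasite	1
T011	55167548	7943	parasite	0
T013	601757575	22726	nonparasite	0
T009	167668415	14439	nonparasite	1
T007	495258108	9667	nonparasite	1
T004	125289654	18769	nonparasite	1
T010	198523375	13556	nonparasite	1
T014	304091805	36266	nonparasite	0
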