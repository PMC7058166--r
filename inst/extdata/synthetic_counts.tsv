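taxon	CDC6/ORC1	ORC2	ORC3	ORC4	ORC5
T012	1	1	1	0	0
T008	2	1	0	1	1
T002	2	1	0	0	2
T001	2	0	0	1	1
T006	4	2	2	2	2
T003	3	2	2	2	2
T005	3	2	0	1	1
T011	3	3	0	1	1
T013	2	3	0	2	1
T009	4	6	1	4	0
T007	2	3	0	1	0
T004	3	2	0	2	1
T010	3	2	0	2	1
T014	2	2	1	1	1
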