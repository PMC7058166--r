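node_id	parasitic	wgd	centrioles
T012	1	none	1
T008	1	none	1
T002	1	none	0
T001	0	none	1
T006	0	none	0
T003	1	none	0
T005	1	none	1
T011	1	none	0
T013	0	none	0
T009	0	reported	1
T007	0	none	1
T004	0	none	1
T010	0	none	1
T014	0	none	0
T001..T014	0	none	NA
T004..T014	0	none	NA
T004..T013	0	none	NA
T001..T012	0	none	NA
T001..T008	0	none	NA
T005..T013	0	none	NA
T004..T010	0	none	NA
T001..T008#2	0	none	NA
T005..T011	1	none	NA
T007..T013	0	none	NA
T007..T009	0	none	NA
T002..T008	1	none	NA
T003..T006	0	reported	NA
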