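((T012,(((T008,T002),T001),(T006,T003))),((((T005,T011),(T013,(T009,T007))),(T004,T010)),T014));
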