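ID   TEST1_HUMAN             Reviewed;         100 AA.
AC   P99901; Q00001;
DE   RecName: Full=Synthetic test protein 1;
DE   AltName: Full=Fixture protein;
DR   PDB; 1ABC; X-ray; 2.00 A; A=5-60.
FT   TRANSMEM        10..30
FT   TRANSMEM        40..62
//
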