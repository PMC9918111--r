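icd9	icd10
5641	K580
5640	K590
311	F329
53081	K219
5533	K449
56210	K573
53089	K229
5308	K20
5750	K810
496	J449
4019	I10
2859	D649
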