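study	uncontaminated	contaminated
ERP014555	915	0
PRJNA396809	260	5
PRJEB7601	55	0
PRJNA1090965	43	0
PRJEB11698	17	3
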