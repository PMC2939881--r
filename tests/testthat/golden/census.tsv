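stratum	N	pairs_total	pairs_SA	pairs_DA	pairs_unknown	frequency	odds
overall	40	5	3	2	0	0.125	1.5
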