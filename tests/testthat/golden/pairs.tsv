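# threshold=0.5
# top_k=1000000
# pairing=either
# seed=NULL
unit_id_a	unit_id_b	article_id_a	article_id_b	ratio_forward	ratio_reverse	pair_ratio	shared_author	granularity	section_class_a	section_class_b
SYN00003:fulltext	SYN00016:fulltext	SYN00003	SYN00016	0.947060811066668	0.947213856410436	0.947213856410436	TRUE	FULLTEXT	NONE	NONE
SYN00007:fulltext	SYN00037:fulltext	SYN00007	SYN00037	0.887963432151291	0.890302501121393	0.890302501121393	FALSE	FULLTEXT	NONE	NONE
SYN00010:fulltext	SYN00039:fulltext	SYN00010	SYN00039	0.945733509945203	0.946133666764785	0.946133666764785	TRUE	FULLTEXT	NONE	NONE
SYN00019:fulltext	SYN00029:fulltext	SYN00019	SYN00029	0.889907660707518	0.889100229140787	0.889907660707518	FALSE	FULLTEXT	NONE	NONE
SYN00021:fulltext	SYN00032:fulltext	SYN00021	SYN00032	0.941240170047855	0.946312450500245	0.946312450500245	TRUE	FULLTEXT	NONE	NONE
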