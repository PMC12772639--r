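source_ns	source_code	target_ns	target_code	table_name
ICD10CM	E11.9	SNOMEDCT	44054006	ICD10CM_SNOMEDCT_REL
ICD10CM	C34.90	SNOMEDCT	363358000	ICD10CM_SNOMEDCT_REL
ICD10CM	N17.9	SNOMEDCT	14669001	ICD10CM_SNOMEDCT_REL
ICD10CM	J18.9	SNOMEDCT	233604007	ICD10CM_SNOMEDCT_REL
ICD10CM	I10	SNOMEDCT	38341003	ICD10CM_SNOMEDCT_REL
LOINC	2160-0	SNOMEDCT	166717003	LNC_SNOMEDCT_MAP
LOINC	6690-2	SNOMEDCT	414478003	LNC_SNOMEDCT_MAP
ICD10CM	Q11.1	SNOMEDCT	7100001	ICD10CM_SNOMEDCT_REL
ICD10CM	Q12.2	SNOMEDCT	7100002	ICD10CM_SNOMEDCT_REL
ICD10CM	Q13.3	SNOMEDCT	7100003	ICD10CM_SNOMEDCT_REL
ICD10CM	Q14.4	SNOMEDCT	7100004	ICD10CM_SNOMEDCT_REL
ICD10CM	Q15.5	SNOMEDCT	7100005	ICD10CM_SNOMEDCT_REL
ICD10CM	Q16.6	SNOMEDCT	7100006	ICD10CM_SNOMEDCT_REL
ICD10CM	Q17.7	SNOMEDCT	7100007	ICD10CM_SNOMEDCT_REL
ICD10CM	Q18.8	SNOMEDCT	7100008	ICD10CM_SNOMEDCT_REL
ICD10CM	Q19.9	SNOMEDCT	7100009	ICD10CM_SNOMEDCT_REL
ICD10CM	Q20.0	SNOMEDCT	7100010	ICD10CM_SNOMEDCT_REL
ICD10CM	Q21.1	SNOMEDCT	7100011	ICD10CM_SNOMEDCT_REL
ICD10CM	Q22.2	SNOMEDCT	7100012	ICD10CM_SNOMEDCT_REL
ICD10CM	Q23.3	SNOMEDCT	7100013	ICD10CM_SNOMEDCT_REL
ICD10CM	Q24.4	SNOMEDCT	7100014	ICD10CM_SNOMEDCT_REL
ICD10CM	Q25.5	SNOMEDCT	7100015	ICD10CM_SNOMEDCT_REL
ICD10CM	Q26.6	SNOMEDCT	7100016	ICD10CM_SNOMEDCT_REL
LOINC	1558-6	SNOMEDCT	8100001	LNC_SNOMEDCT_MAP
LOINC	4548-4	SNOMEDCT	8100002	LNC_SNOMEDCT_MAP
LOINC	2823-3	SNOMEDCT	8100003	LNC_SNOMEDCT_MAP
LOINC	1742-6	SNOMEDCT	8100004	LNC_SNOMEDCT_MAP
LOINC	1975-2	SNOMEDCT	8100005	LNC_SNOMEDCT_MAP
LOINC	777-3	SNOMEDCT	8100006	LNC_SNOMEDCT_MAP
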