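namespace	code	preferred_term	semantic_type
SNOMEDCT	44054006	Type 2 Diabetes Mellitus	disease
RXNORM	860975	metformin hydrochloride 500 mg 24HR extended-release oral tablet	drug
RXNORM	6809	Metformin	drug
RXNORM	1547545	Pembrolizumab	drug
SNOMEDCT	363358000	Lung Cancer	disease
SNOMEDCT	14669001	Acute Kidney Injury	disease
SNOMEDCT	233604007	Pneumonia	disease
SNOMEDCT	38341003	Hypertension	disease
SNOMEDCT	166717003	Elevated Serum Creatinine	lab
SNOMEDCT	414478003	Elevated White Blood Cell Count	lab
RXNORM	910001	Abexonib	drug
RXNORM	910002	Veltramab	drug
RXNORM	910003	Cormipril	drug
RXNORM	910004	Dulzastatin	drug
RXNORM	910005	Ephranib	drug
RXNORM	910006	Fenvomab	drug
RXNORM	910007	Galtopril	drug
RXNORM	910008	Hyrrastatin	drug
RXNORM	910009	Ivocanib	drug
RXNORM	910010	Julmamab	drug
RXNORM	910011	Kevrapril	drug
RXNORM	910012	Lomzastatin	drug
RXNORM	910013	Mirtonib	drug
RXNORM	910014	Nexvamab	drug
RXNORM	910015	Orlidpril	drug
RXNORM	910016	Pavnostatin	drug
RXNORM	910017	Quiltanib	drug
RXNORM	910018	Rexnamab	drug
RXNORM	910019	Solvapril	drug
RXNORM	910020	Trivostatin	drug
RXNORM	910021	Ulzomnib	drug
RXNORM	910022	Vepramab	drug
RXNORM	910023	Wolxapril	drug
RXNORM	910024	Xendastatin	drug
RXNORM	910025	Yorvinib	drug
RXNORM	910026	Zeltamab	drug
RXNORM	910027	Brivopril	drug
RXNORM	910028	Cestrastatin	drug
SNOMEDCT	7100001	Aldermann Syndrome	disease
SNOMEDCT	7100002	Bextrel Disease	disease
SNOMEDCT	7100003	Corvan Syndrome	disease
SNOMEDCT	7100004	Delmar Disease	disease
SNOMEDCT	7100005	Ellory Syndrome	disease
SNOMEDCT	7100006	Fenwick Disease	disease
SNOMEDCT	7100007	Garmon Syndrome	disease
SNOMEDCT	7100008	Hastel Disease	disease
SNOMEDCT	7100009	Imbren Syndrome	disease
SNOMEDCT	7100010	Jorvik Disease	disease
SNOMEDCT	7100011	Kestner Syndrome	disease
SNOMEDCT	7100012	Lomond Disease	disease
SNOMEDCT	7100013	Merrow Syndrome	disease
SNOMEDCT	7100014	Norvell Disease	disease
SNOMEDCT	7100015	Ostrand Syndrome	disease
SNOMEDCT	7100016	Pellard Disease	disease
SNOMEDCT	1100001	Chronic Fatigue	symptom
SNOMEDCT	1100002	Night Sweats	symptom
SNOMEDCT	1100003	Persistent Cough	symptom
SNOMEDCT	1100004	Joint Stiffness	symptom
SNOMEDCT	1100005	Dizziness	symptom
SNOMEDCT	1100006	Blurred Vision	symptom
SNOMEDCT	1100007	Chest Tightness	symptom
SNOMEDCT	1100008	Morning Headache	symptom
SNOMEDCT	2100001	Nausea	side_effect
SNOMEDCT	2100002	Skin Rash	side_effect
SNOMEDCT	2100003	Dry Mouth	side_effect
SNOMEDCT	2100004	Insomnia	side_effect
SNOMEDCT	2100005	Peripheral Edema	side_effect
SNOMEDCT	2100006	Hair Loss	side_effect
SNOMEDCT	2100007	Muscle Cramps	side_effect
SNOMEDCT	2100008	Mild Fever	side_effect
SNOMEDCT	2100009	Loss of Appetite	side_effect
SNOMEDCT	2100010	Tremor	side_effect
SNOMEDCT	3100001	Complete Remission	outcome
SNOMEDCT	3100002	Partial Response	outcome
SNOMEDCT	3100003	Disease Progression	outcome
SNOMEDCT	3100004	Improved Survival	outcome
SNOMEDCT	3100005	Symptom Relief	outcome
SNOMEDCT	3100006	Stable Disease	outcome
SNOMEDCT	8100001	Fasting Glucose	lab
SNOMEDCT	8100002	Hemoglobin A1c	lab
SNOMEDCT	8100003	Serum Potassium	lab
SNOMEDCT	8100004	Alanine Aminotransferase	lab
SNOMEDCT	8100005	Total Bilirubin	lab
SNOMEDCT	8100006	Platelet Count	lab
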