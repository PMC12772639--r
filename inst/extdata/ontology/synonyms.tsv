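namespace	code	synonym
RXNORM	860975	Metformin 500 mg extended-release
SNOMEDCT	44054006	Type II Diabetes
SNOMEDCT	7100001	Aldermann Syndrome of Type 2
SNOMEDCT	7100002	Bextrel Disease of Type 3
SNOMEDCT	7100003	Corvan Syndrome of Type 1
SNOMEDCT	7100004	Delmar Disease of Type 2
SNOMEDCT	7100005	Ellory Syndrome of Type 3
SNOMEDCT	7100006	Fenwick Disease of Type 1
SNOMEDCT	7100007	Garmon Syndrome of Type 2
SNOMEDCT	7100008	Hastel Disease of Type 3
SNOMEDCT	7100009	Imbren Syndrome of Type 1
SNOMEDCT	7100010	Jorvik Disease of Type 2
SNOMEDCT	7100011	Kestner Syndrome of Type 3
SNOMEDCT	7100012	Lomond Disease of Type 1
SNOMEDCT	7100013	Merrow Syndrome of Type 2
SNOMEDCT	7100014	Norvell Disease of Type 3
SNOMEDCT	7100015	Ostrand Syndrome of Type 1
SNOMEDCT	7100016	Pellard Disease of Type 2
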