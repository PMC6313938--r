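Cre02.g076950	Y	22
Cre04.g213400	Y	23
Cre07.g329500	Y	29
Cre10.g459450	Y	30
Cre05.g242100	Y	26
Cre05.g242750	Y	23
Cre19.g750447	Y	26
Cre14.g628800	Y	47
Cre01.g049950	N	-
Cre03.g145827	N	-
Cre16.g685250	N	-
Cre17.g708400	N	-
Cre17.g735450	N	-
Cre03.g190250	N	-
Cre13.g585800	N	-
Cre16.g675350	N	-
Cre17.g713600	N	-
Cre03.g170300	N	-
Cre05.g242700	N	-
Cre05.g242856	N	-
Cre09.g406700	N	-
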