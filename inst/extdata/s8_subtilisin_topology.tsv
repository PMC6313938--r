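Cre02.g076950	-
Cre04.g213400	-
Cre07.g329500	-
Cre10.g459450	-
Cre05.g242100	-
Cre05.g242750	-
Cre19.g750447	-
Cre14.g628800	1719-1741
Cre01.g049950	37-59
Cre03.g145827	45-67
Cre16.g685250	55-77
Cre17.g708400	451-473
Cre17.g735450	138-160
Cre03.g190250	1149-1171
Cre13.g585800	-
Cre16.g675350	-
Cre17.g713600	-
Cre03.g170300	-
Cre05.g242700	-
Cre05.g242856	-
Cre09.g406700	-
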