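sample_id	subtype	age	sex	ethnicity	hb	wbc	platelet	hsm	constitutional_symptoms	smoker
01	ET	30	M	Malay	17.1	7.6	1730	No	No	No
02	ET	50	F	Chinese	13.2	10.9	776	No	No	No
03	ET	79	M	Malay	11.1	24.5	869	No	No	Yes
04	PV	54	M	Chinese	18.9	17.2	426	No	Yes	Yes
05	PV	66	F	Chinese	19.3	18.1	423	No	Yes	No
06	PV	73	M	Dutch	20	9	334	No	Yes	Yes
07	Pre-PMF	50	M	Chinese	15	17.8	859	No	Yes	Yes
08	Pre-PMF	50	F	Malay	8.7	58.4	1099	No	Yes	No
09	Overt-PMF	46	M	Malay	7.1	3.9	452	Yes	No	No
10	Overt-PMF	63	M	Chinese	7.3	5.5	54	No	Yes	Yes
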