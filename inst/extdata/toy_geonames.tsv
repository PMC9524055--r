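3017382	France	France	République française,Francia,Frankreich,Franca	46.0	2.0	A	PCLI	FR		00				66987244		375	Europe/Paris	2020-01-01
2510769	Spain	Spain	España,Espagne,Espanha,Spanien	40.0	-4.0	A	PCLI	ES		00				46505963		650	Europe/Madrid	2020-01-01
2921044	Germany	Germany	Deutschland,Allemagne,Alemania,Alemanha	51.5	10.5	A	PCLI	DE		00				82927922		303	Europe/Berlin	2020-01-01
3175395	Italy	Italy	Italia,Italie,Italien	42.8	12.8	A	PCLI	IT		00				60431283		380	Europe/Rome	2020-01-01
2264397	Portugal	Portugal	Portogallo,Portugalia	39.6	-8.1	A	PCLI	PT		00				10283822		372	Europe/Lisbon	2020-01-01
2635167	United Kingdom	United Kingdom	UK,Great Britain,Royaume-Uni,Reino Unido	54.8	-2.7	A	PCLI	GB		00				66488991		162	Europe/London	2020-01-01
6252001	United States	United States	USA,United States of America,Estados Unidos,États-Unis	39.8	-98.5	A	PCLI	US		00				327167434		543	America/Chicago	2020-01-01
3469034	Brazil	Brazil	Brasil,Brésil,Brasilien	-10.8	-52.9	A	PCLI	BR		00				209469333		250	America/Sao_Paulo	2020-01-01
3865483	Argentina	Argentina	República Argentina,Argentine	-34.0	-64.0	A	PCLI	AR		00				44494502		595	America/Buenos_Aires	2020-01-01
3625428	Venezuela	Venezuela	República Bolivariana de Venezuela	8.0	-66.0	A	PCLI	VE		00				28870195		430	America/Caracas	2020-01-01
1814991	China	China	Chine,Zhongguo,República Popular China	35.0	105.0	A	PCLI	CN		00				1392730000		1847	Asia/Shanghai	2020-01-01
1269750	India	India	Inde,Bharat,Índia	22.0	79.0	A	PCLI	IN		00				1352617328		621	Asia/Kolkata	2020-01-01
2328926	Nigeria	Nigeria	Nigéria,Nijeriya	10.0	8.0	A	PCLI	NG		00				195874740		380	Africa/Lagos	2020-01-01
3012874	Île-de-France	Ile-de-France	Region Parisienne,Ile de France	48.5	2.5	A	ADM1	FR		11				12117132		90	Europe/Paris	2020-01-01
2593111	Castilla-La Mancha	Castilla-La Mancha	Castille-La Manche,Castela-Mancha	39.5	-3.0	A	ADM1	ES		54				2026807		700	Europe/Madrid	2020-01-01
5332921	California	California	Californie,Califórnia	37.3	-119.6	A	ADM1	US		CA				39512223		884	America/Los_Angeles	2020-01-01
3435907	Buenos Aires Province	Buenos Aires Province	Provincia de Buenos Aires	-36.0	-60.0	A	ADM1	AR		01				17569053		50	America/Buenos_Aires	2020-01-01
2988507	Paris	Paris	Lutetia,París,Parigi,Pariz	48.85341	2.3488	P	PPLC	FR		11				2138551		42	Europe/Paris	2020-01-01
3117735	Madrid	Madrid	Madrid City,Madrid Capital	40.4165	-3.70256	P	PPLC	ES		29				3255944		665	Europe/Madrid	2020-01-01
3128760	Barcelona	Barcelona	Barcelone,Barna	41.38879	2.15899	P	PPLA	ES		56				1621537		12	Europe/Madrid	2020-01-01
2267057	Lisbon	Lisbon	Lisboa,Lisbonne,Lisbona	38.71667	-9.13333	P	PPLC	PT		14				517802		45	Europe/Lisbon	2020-01-01
2643743	London	London	Londres,Londra,Londinium	51.50853	-0.12574	P	PPLC	GB		ENG				7556900		25	Europe/London	2020-01-01
2950159	Berlin	Berlin	Berlín,Berlim,Berlino	52.52437	13.41053	P	PPLC	DE		16				3426354		74	Europe/Berlin	2020-01-01
3169070	Rome	Rome	Roma,Rom	41.89193	12.51133	P	PPLC	IT		07				2318895		20	Europe/Rome	2020-01-01
2519402	Ciudad Real	Ciudad Real	Cidade Real	38.98626	-3.92907	P	PPLA	ES		54				74014		625	Europe/Madrid	2020-01-01
3435910	Buenos Aires	Buenos Aires	Capital Federal,Baires,Buenos Ayres	-34.61315	-58.37723	P	PPLC	AR		07				3054300		31	America/Buenos_Aires	2020-01-01
5128581	New York City	New York City	New York,NYC,Nueva York,Nova Iorque	40.71427	-74.00597	P	PPL	US		NY				8175133		10	America/New_York	2020-01-01
3448439	São Paulo	Sao Paulo	Sampa,San Pablo	-23.5475	-46.63611	P	PPLA	BR		27				10021295		769	America/Sao_Paulo	2020-01-01
2332459	Lagos	Lagos	Eko,Lagos City	6.45407	3.39467	P	PPLA	NG		05				8789133		11	Africa/Lagos	2020-01-01
1275339	Mumbai	Mumbai	Bombay,Bombaim	19.07283	72.88261	P	PPL	IN		16				12691836		8	Asia/Kolkata	2020-01-01
3646738	Caracas	Caracas	Santiago de León de Caracas	10.48801	-66.87919	P	PPLC	VE		25				3000000		900	America/Caracas	2020-01-01
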