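region	type	haplogroup	count
Bocas del Toro	province	A2	28
Bocas del Toro	province	B2	11
Bocas del Toro	province	L1	2
Bocas del Toro	province	L2	11
Bocas del Toro	province	L3	8
Chiriqui	province	A2	227
Chiriqui	province	B2	91
Chiriqui	province	C1	4
Chiriqui	province	D1	5
Chiriqui	province	L0	6
Chiriqui	province	L1	18
Chiriqui	province	L2	16
Chiriqui	province	L3	6
Chiriqui	province	HV	3
Chiriqui	province	JT	2
Cocle	province	A2	50
Cocle	province	B2	39
Cocle	province	C1	7
Cocle	province	D1	1
Cocle	province	L1	1
Cocle	province	L2	3
Cocle	province	L3	4
Cocle	province	HV	2
Cocle	province	JT	1
Cocle	province	N1'2	1
Colon	province	A2	19
Colon	province	B2	11
Colon	province	C1	1
Colon	province	L1	3
Colon	province	L2	15
Colon	province	L3	7
Colon	province	U	1
Darien	province	A2	13
Darien	province	B2	8
Darien	province	C1	3
Darien	province	D1	1
Darien	province	L1	5
Darien	province	L2	9
Darien	province	L3	4
Darien	province	HV	1
Darien	province	U	1
Herrera	province	A2	71
Herrera	province	B2	28
Herrera	province	C1	4
Herrera	province	L2	5
Herrera	province	L3	7
Herrera	province	U	1
Los Santos	province	A2	69
Los Santos	province	B2	30
Los Santos	province	C1	3
Los Santos	province	D1	1
Los Santos	province	L0	1
Los Santos	province	L2	3
Los Santos	province	L3	9
Los Santos	province	HV	4
Los Santos	province	U	1
Los Santos	province	G	1
Panama	province	A2	78
Panama	province	B2	46
Panama	province	C1	5
Panama	province	D1	3
Panama	province	L1	9
Panama	province	L2	11
Panama	province	L3	17
Panama	province	HV	8
Panama	province	U	1
Veraguas	province	A2	77
Veraguas	province	B2	65
Veraguas	province	C1	10
Veraguas	province	L0	1
Veraguas	province	L1	1
Veraguas	province	L2	4
Veraguas	province	L3	4
Veraguas	province	HV	4
Embera-Wounaan	comarca	A2	7
Embera-Wounaan	comarca	B2	16
Embera-Wounaan	comarca	C1	18
Embera-Wounaan	comarca	D1	3
Kuna Yala	comarca	A2	37
Kuna Yala	comarca	B2	6
Kuna Yala	comarca	C1	4
Kuna Yala	comarca	L2	1
Ngabe-Bugle	comarca	A2	13
Ngabe-Bugle	comarca	B2	13
Ngabe-Bugle	comarca	C1	1
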