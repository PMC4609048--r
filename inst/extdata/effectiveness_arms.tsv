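study	alternative	successes	n	route	duration_days	assessment_day
Durelli 1986	HIGH_DOSE	10	11	IV	15	15
Milligan 1987	HIGH_DOSE	10	13	IV	5	28
La Mantia 1994	HIGH_DOSE	8	10	IV	14	14
Barnes 1997	HIGH_DOSE	13	38	IV	3	28
Sellebjerg 1998	HIGH_DOSE	14	26	PO	15	21
Visser 2004	HIGH_DOSE	6	9	IV	5	28
Ramo-Tello 2013	HIGH_DOSE	15	23	IV	3	28
Ramo-Tello 2013	HIGH_DOSE	15	22	PO	3	28
Milanese 1989	LOW_DOSE	3	10	IV	14	30
La Mantia 1994	LOW_DOSE	6	10	IV	14	14
Barnes 1997	LOW_DOSE	20	42	PO	21	28
Miller 1961	PLACEBO	4	18	IM	21	21
Rose 1970	PLACEBO	39.25	94	IM	14	28
Durelli 1986	PLACEBO	4	10	IV	15	15
Milligan 1987	PLACEBO	2	9	IV	5	28
Sellebjerg 1998	PLACEBO	6	25	PO	15	21
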