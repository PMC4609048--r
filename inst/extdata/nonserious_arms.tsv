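study	alternative	successes	n	route	duration	followup_days
Abbruzzese 1983	HIGH_DOSE	3	30	IV	15	NA
Durelli 1986	HIGH_DOSE	9.2	13	IV	15	15
Thompson 1989	HIGH_DOSE	1	29	IV	3	84
Sellebjerg 1998	HIGH_DOSE	23	26	PO	15	56
La Mantia 1994	HIGH_DOSE	0	10	IV	14	14
Soelberg-Sorensen 2004	HIGH_DOSE	30	40	IV	3	182
Martinelli 2009	HIGH_DOSE	11	20	IV	5	28
Martinelli 2009	HIGH_DOSE	15	20	PO	5	28
Ramo-Tello 2013	HIGH_DOSE	24	24	IV	3	28
Ramo-Tello 2013	HIGH_DOSE	24	25	PO	3	28
Shaygannejad 2013	HIGH_DOSE	58	64	IV	13-20	90
Rose 1970	PLACEBO	8	94	IM	14	28
Durelli 1986	PLACEBO	5	10	IV	15	15
Sellebjerg 1998	PLACEBO	8	25	PO	15	56
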