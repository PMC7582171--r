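family	group	E_californica	A_thaliana	V_vinifera
AP2	NA	20	18	20
DREB	I	5	10	5
DREB	II	11	15	8
DREB	III	23	23	22
DREB	IV	8	9	5
ERF	V	6	5	11
ERF	VI	10	8	5
ERF	VII	5	5	3
ERF	VIII	15	15	11
ERF	IX	13	17	40
ERF	X	2	8	10
ERF	VI-L	8	4	2
ERF	Xb-L	0	3	0
ERF	single	1	0	0
RAV	NA	5	6	6
Soloist	NA	2	1	1
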