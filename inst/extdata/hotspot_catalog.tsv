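reference_position	segment	kinase	mutation	activation_status	n_mutations_printed	n_drivers_printed
L718	P-loop	ABL	L248V	activating	4	4
L718	P-loop	BRAF	I462S	activating	4	4
L718	P-loop	EGFR	L718P	activating	4	4
L718	P-loop	JAK3	L527P	activating	4	4
G721	P-loop	EGFR	G721	activating	5	4
G721	P-loop	BRAF	G464A/E/R/V	activating	5	4
G721	P-loop	caMLCK	G601E	activating	5	4
G721	P-loop	MLK2	G107E	activating	5	4
G721	P-loop	NDR2	G99A	activating	5	4
G721	P-loop	AurC	G52E	activating	5	4
T790	Hinge	EGFR	T790M	activating	6	5
T790	Hinge	ABL	T315I/N	activating	6	5
T790	Hinge	FGFR4	V550M	activating	6	5
T790	Hinge	KIT	T670E	activating	6	5
T790	Hinge	PDGFRa	T674I	activating	6	5
T790	Hinge	NEK11	T108M	activating	6	5
G796	Hinge	EGFR	G796S	activating	5	5
G796	Hinge	ABL	G321E	activating	5	5
G796	Hinge	ErbB2	G804S	activating	5	5
G796	Hinge	IRR	G1065E	activating	5	5
G796	Hinge	LKB1	G135R	activating	5	5
D855	Activation	BRAF	D594E	inactivating	5	5
D855	Activation	DAPK3	D161N	inactivating	5	5
D855	Activation	HCK	D378G	inactivating	5	5
D855	Activation	LKB1	D194V	inactivating	5	5
D855	Activation	LYN	D385Y	inactivating	5	5
G857	Activation	BRAF	G596R	inactivating	6	5
G857	Activation	EPHA3	G766E	inactivating	6	5
G857	Activation	FYN	G410R	inactivating	6	5
G857	Activation	JNK1	G171S	inactivating	6	5
G857	Activation	MAST2	G655A	inactivating	6	5
G857	Activation	CDK11	G175S	inactivating	6	5
L858	Activation	EGFR	L858R	activating	3	3
L858	Activation	BRAF	L596V	activating	3	3
L858	Activation	ErbB2	L866R	activating	3	3
L861	Activation	EGFR	L861Q/R	activating	8	8
L861	Activation	ABL	L387M	activating	8	8
L861	Activation	BRAF	V600D/E/G/K/L/M	activating	8	8
L861	Activation	ErbB2	L869Q	activating	8	8
L861	Activation	FLT3	D835E/F/H/N/V/Y	activating	8	8
L861	Activation	KIT	D816E/F/V/H/I/N/V	activating	8	8
L861	Activation	MET	D1246H/N/V	activating	8	8
L861	Activation	PDGFRa	D842I/V/Y	activating	8	8
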