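kinase	mutation	activation_status
ABL	L248V	activating
ABL	T315I/L/N	activating
ABL	G321E	activating
ABL	Y353H	activating
ABL	L387M	activating
EGFR	L718P	activating
EGFR	G719C/A/R/D/V/S	activating
EGFR	G721D	activating
EGFR	L747S/P/F	activating
EGFR	V765M	activating
EGFR	V769L	activating
EGFR	T790M	activating
EGFR	G796S	activating
EGFR	L833V	activating
EGFR	T854A	activating
EGFR	D855	inactivating
EGFR	L858R	activating
EGFR	L861Q/R	activating
BRAF	G466E/V	inactivating
BRAF	D594E/V	inactivating
BRAF	G596R	inactivating
BRAF	L597V/S/Q/R	activating
BRAF	A598V	activating
BRAF	T599I/A	activating
BRAF	V600E/K/R/M	activating
FGFR2	I548V	activating
FGFR2	N550K	activating
FGFR2	E565G/A	activating
FGFR2	N549H	activating
FGFR2	N540K	activating
FGFR2	K526E	activating
FGFR2	K660E	activating
FGFR2	R678G	activating
FGFR2	K641R	activating
FGFR2	G663E	activating
FGFR2	E636K	inactivating
FGFR2	M640I	inactivating
FGFR2	I642V	inactivating
FGFR2	R759Q	inactivating
FGFR2	E475K	inactivating
FGFR2	D530N	inactivating
FGFR2	A648T	inactivating
FGFR2	G701S	inactivating
FGFR3	I538V	activating
FGFR3	N540K	activating
FGFR3	K650E	activating
FGFR3	K508	inactivating
FGFR4	P712T	activating
FGFR4	H713R	activating
FGFR4	S772N	activating
FGFR4	D127H	activating
FGFR4	K503M	inactivating
MAP2K4	Q142L	activating
MAP2K4	R134Q	activating
MAP2K4	R154W	inactivating
MAP2K4	P326L	inactivating
MAP2K4	S251N	inactivating
MAP2K4	N234I	inactivating
DAPK3	T112M	inactivating
DAPK3	D161N	inactivating
DAPK3	P216S	inactivating
HCK	D378G	inactivating
LYN	D385G	inactivating
LKB1	D194V	inactivating
FYN	G410R	inactivating
EPHA3	R728L	inactivating
EPHA3	K761N	inactivating
EPHA3	D678E	inactivating
EPHA3	G766E	inactivating
EPHA3	D806N	inactivating
MAPK8	G171S	inactivating
CDK11	G175S	inactivating
MAST205	G655A	inactivating
TRKB	T695I	inactivating
TRKB	D751N	inactivating
ERBB2	I767M	activating
ERBB2	D769H/Y	activating
ERBB2	V773A	activating
ERBB2	V777L	activating
ERBB2	T798M	activating
ERBB2	G804S	activating
ERBB2	Y835F	activating
ERBB2	V842I	activating
ERBB2	T862A	activating
ERBB2	L866R	activating
ERBB2	L869Q	activating
ERBB2	R896C	activating
ERBB2	K753M	inactivating
ERBB3	V714M	activating
ERBB3	Q809R	activating
ERBB3	V855A	activating
ERBB3	S846I	activating
ERBB3	E298C	activating
ERBB4	V696I	none
ERBB4	A748S	none
ERBB4	E785K	none
ERBB4	R757Q	none
ERBB4	P829Q	none
ERBB4	T901M	none
ERBB4	K726R	inactivating
ERBB4	D818N	inactivating
ERBB4	D836Q	inactivating
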