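symbol	query_ids	group	meiosis_specific
SPO11	SPO11_q	double-strand breaks	TRUE
MRE11	MRE11_q	double-strand breaks	FALSE
RAD50	RAD50_q	double-strand breaks	FALSE
ATM	ATM_q	double-strand breaks	FALSE
DNA2	DNA2_q	double-strand breaks	FALSE
REC114	REC114_q	double-strand breaks	FALSE
HOP1	HOP1_q	synaptonemal complex	TRUE
RED1	RED1_q	synaptonemal complex	TRUE
PCH2	PCH2_q	synaptonemal complex	TRUE
ZIP1	ZIP1_q	ZMM proteins	TRUE
ZIP2	ZIP2_q	ZMM proteins	TRUE
ZIP3	ZIP3_q	ZMM proteins	TRUE
ZIP4	ZIP4_q	ZMM proteins	TRUE
MER3	MER3_q	ZMM proteins	TRUE
MSH4	MSH4_q	ZMM proteins	TRUE
MSH5	MSH5_q	ZMM proteins	TRUE
HOP2	HOP2_q	homologous recombination	TRUE
MND1	MND1_q	homologous recombination	TRUE
DMC1	DMC1_q	homologous recombination	TRUE
RAD51A	RAD51A_q	homologous recombination	FALSE
ATR	ATR_q	homologous recombination	FALSE
RAD17	RAD17_q	homologous recombination	FALSE
SMC1	SMC1_q	cohesin complex	FALSE
SMC3	SMC3_q	cohesin complex	FALSE
REC8	REC8_q	cohesin complex	TRUE
SMC5	SMC5_q	cohesin complex	FALSE
SMC6	SMC6_q	cohesin complex	FALSE
SLX4	SLX4_q	crossover I	FALSE
MLH1	MLH1_q	crossover I	FALSE
MLH3	MLH3_q	crossover I	FALSE
MUS81	MUS81_q	crossover II	FALSE
MMS4	MMS4_q	crossover II	FALSE
SLX1	SLX1_q	crossover II	FALSE
SGS1	SGS1_q	crossover II	FALSE
MSH2	MSH2_q	mismatch correction	FALSE
MSH3	MSH3_q	mismatch correction	FALSE
MSH6	MSH6_q	mismatch correction	FALSE
PMS1	PMS1_q	mismatch correction	FALSE
PMS2	PMS2_q	mismatch correction	FALSE
EXO1	EXO1_q	mismatch correction	FALSE
HAP2	HAP2_q	syngamy	TRUE
GEX1	GEX1_q	syngamy	TRUE
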