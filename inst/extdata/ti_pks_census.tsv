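genome	species	clusters	t1_total	nr	r	pr	hybrid	nrps	nrps_putative
alesarpred	Alectoria sarmentosa	36	12	5	7	0	1	2	12
bacgigpred	Bacidia gigantensis	31	11	7	4	0	1	5	10
bacrubpred	Bacidia rubella	31	10	6	4	0	0	3	7
clagrapred	Cladonia grayi	48	21	8	12	1	0	2	11
clamacpred	Cladonia macilenta	55	25	15	10	0	2	3	9
clametpred	Cladonia metacorallifera	51	24	10	14	0	1	1	11
claranpred	Cladonia rangiferina	68	34	14	20	0	2	3	12
clauncpred	Cladonia uncialis	61	30	15	14	1	2	1	11
cyaastpred	Cyanodermella asteris	35	11	5	5	1	1	3	10
dibbaepred	Dibaeis baeomyces	55	27	11	15	1	0	4	14
endpuspred	Endocarpon pusillum	32	14	4	9	1	1	3	4
eveprupred	Evernia prunastri	86	36	16	19	1	4	3	20
grascrpred	Graphis scripta	54	21	6	15	0	1	6	14
gyaflapred	Gyalolechia flavorubescens	41	16	8	8	0	1	3	8
lashispred	Lasallia hispanica	28	15	8	6	1	1	0	3
laspuspred	Lasallia pustulata	26	17	9	7	1	0	0	4
letcolpred	Letharia columbiana	43	14	7	7	0	2	3	6
letluppred	Letharia lupina	48	18	11	7	0	2	3	11
psefurpred	Pseudevernia furfuracea	48	26	8	18	0	3	3	11
ramintpred	Ramalina intermedia	54	31	13	17	1	3	5	9
ramperpred	Ramalina peruviana	43	17	9	7	1	1	4	10
usnhakpred	Usnea hakonensis	70	23	10	12	1	3	5	22
xanelepred	Xanthoria elegans	63	25	7	18	0	1	7	17
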