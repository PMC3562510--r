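tre	variant	consensus	contrast	occ_case	occ_control
DMRT	1	ctttcttGTAActtttgagaa	burn_vs_no_burn	68	1
BRNF	1	tctggatctatTGATttga	burn_vs_no_burn	35	4
BCL6	1	ctctttcTGGAaactga	burn_vs_no_burn	31	3
TF2D	1	gctctggtactttttcatcccttgcaaaatGGCGttact	burn_vs_no_burn	27	1
PTF1	1	gccaTCTGttcttggccctga	burn_vs_no_burn	28	1
MYT1	1	tgagAGCTcagct	burn_vs_no_burn	27	2
AIRE	1	gtatttctcggtcatttGGGGaaactg	burn_vs_no_burn	19	0
ZNFP	1	cacaCACCtggtc	burn_vs_no_burn	22	0
NRF1	1	gggGCCCaggcgcttga	burn_vs_no_burn	21	1
PAX2	1	gttattcggggaacctgAAACtg	B_vs_T	32	13
HAML	1	ctgaGTGGttagttc	B_vs_T	35	8
NKXH	1	acttttgaGAACttagctc	B_vs_T	33	10
HOMF	1	taatctTTAActgttaatc	B_vs_T	16	37
SORY	1	gttctaaaCAATgtctattttca	B_vs_T	14	28
HEAT	1	gagagggtctaatGAAGgttcaaca	B_vs_T	10	30
MAZF	1	atggGAGGggtac	B_vs_T	8	18
MAZF	2	gtacGAGGagagg	B_vs_T	8	18
MEF2	1	acaatgtCTATtttcaagaaatg	B_vs_T	5	19
GATA	1	tttAGATctaaac	B_vs_T	6	16
CART	1	gggtcTAATgaaggttcaaca	B_vs_T	8	16
HOXF	1	gggtcTAATgaaggttcaa	B_vs_T	7	17
LHXF	1	gagagggtcTAATgaaggttcaa	B_vs_T	7	16
FXRE	1	AGGTgcttgacca	B_vs_T	5	19
GRHL	1	cacacaGGTTcaa	B_vs_T	7	16
NKX6	1	atctTTAActgttaa	B_vs_T	6	16
CEBP	1	aaggttcaGCAAtgg	B_vs_T	6	15
FKHD	1	tagttcTAAAcaatgtc	B_vs_T	5	16
PDX1	1	gaaagagtcTAATgaaggt	B_vs_T	5	15
RXRF	1	cacagGTTCaaggagtggccagagc	B_vs_T	5	16
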