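# Default GC-MS fragment library (MOX-TBDMS derivatization, [M-57]+
# ions).  Reconstruction: the monitored SIM ions of the original study
# are unpublished, so each measured metabolite is represented by one
# full-skeleton fragment with a plausible derivatized ion formula.
# atoms: 1-based carbons of the parent metabolite included in the ion.
fragment_id	metabolite	atoms	formula
PYR_mox_tbdms	PYR.obs	1,2,3	C9H18NO3Si
LAC_2tbdms	LAC.c	1,2,3	C11H25O3Si2
ALA_2tbdms	ALA.obs	1,2,3	C11H26NO2Si2
G3P_3tbdms	G3P.c	1,2,3	C15H38O6PSi3
PG3_3tbdms	PG3.c	1,2,3	C15H36O7PSi3
PEP_2tbdms	PEP.c	1,2,3	C11H24O6PSi2
MAL_3tbdms	MAL.obs	1,2,3,4	C18H37O5Si3
ASP_3tbdms	ASP.obs	1,2,3,4	C18H38NO4Si3
GLU_3tbdms	GLU.obs	1,2,3,4,5	C19H40NO4Si3
GLN_3tbdms	GLN.c	1,2,3,4,5	C19H41N2O3Si3
CIT_4tbdms	CIT.obs	1,2,3,4,5,6	C26H55O7Si4
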