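target	direction	sequence_5to3	note
ACTB	fwd	TACAATGAGCTGCGTGTGGC	housekeeping control
ACTB	rev	CGGACTCGTCATACTCCTGC	housekeeping control
HERV-FRD	fwd	CCCTCACCCCCTTATTTCAT	
HERV-FRD	rev	TTTGAAGGACTACGGCTGCT	
HERV-FRD	fwd	ACCATGGGCCTGCTCCT	ORF cloning pair
HERV-FRD	rev	TCCTCCTTAGAAGGGTGACTC	ORF cloning pair
EWSR1-FLI1	fwd	GGCCAAGATCAATCCTCCAT	
EWSR1-FLI1	rev	ATGGAGGATTGATCTTGGCC	
LIPI	fwd	AACCAGCCCAATCAGACAAC	
LIPI	rev	AATCACTGGCCAGGACATTC	
NEDD9	fwd	CACCGCAGTGCTTAATGCTG	
NEDD9	rev	TCACGGGGGTTATCACCTTTTT	
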