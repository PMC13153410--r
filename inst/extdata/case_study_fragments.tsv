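peptide_id	peptide	chrom	start	end	strand	tumor_reads	total_reads	validation_sequence
P1	VILPPQPPK	chr11	70055837	70055863	-	83	151	TTTTTTTAGAGATGAGGTTTCCCTATGTTGGCGAGGCTGGCCTCAAACTCCTGGGTTCAAGTAATCCTCCCACCTCAGCCTCCCAAAGTGCAGGGATTACAGATGAGAGCCACTGCACCTGGCCTAGCGCCCAGTTTTAATTGAGG
P2	AVLLPQPPK	chr8	103996760	103996786	+	8	8	CAAGCTGGAGTGCAGTGGCACAATCTCGGGTCACTGCAACCTCCGCCTCCCAGATTCAAGCAGTTCTCCTGCCTCAGCCTCCCAAATAGCTGGGATTACAGGCACCTGCCACCATGTCTGGCTAAATTTTTGTATTTTTTTAGTAG
P3	GILLPQPPK	chr1	155663642	155663668	-	9	14	ACAGGCTGGAGTGCAATGGCGCAATCTCAGCTCACTGCAACCTCCGCCCCCCAAGTTCAAGGGATTCTCCTGCCTCAGCCTCCCAAGTAGCTGCGATTACAGGCATGTGCCACCACACCCTGCTAATTTTGTATTTTTAGTAGAGA
PO1	ATFLGSLTWK	chr19	53460452	53460481	+	1	1	AATAAAGCCACTTCCTTCTTTAATCCGTTGTCTGAGAGGTACTGTCTGCGGCTCGTCATGCTACATTTCTTGGTTCCCTGACTTGGAAGCGAGGTAATTAACAGAAGGTCGAGGCAACCCCTTAGGTGACTTAGGCCTGCCCTTTGGAG
PO2	ATFLGSLTGK	chr13	41454938	41454967	-	29	37	GAATAAAGCTACTTCCTTTCTCAACCTGGTGTCTGAGGGGTTTTGTCCACAGCTTGTCCTGCTACATTTCTTGGTTCTCTGACTGGGAAGCGAGGTGATTAGCAGACAGTCAAGGCAGCCCCTTAGGTGGCTCAGGCCTGCCCTGTGGA
PO3	KLIAGLIFLK	chr1	206284989	206285018	-	17	46	CAAGCCCTGCTCCAGTCACACCCGGAAGCTGACTGGTCCACGCACAGCTGAAGCATGAGGAAACTCATCGCGGGACTAATTTTCCTTAAAATTTAGACTTGCACAGTAAGGACTTCAACTGACCTTCCTCAGACTGAGAACTGTTTCCA
PO4	NEAIEQVRAICLRAW	chr1	155603245	155603289	-	47	48	GATCAACTATTAGGAATAGGTCAAAATTGGAGTACTATTAGTCAACAAGCATTAATGCAAAATGAGGCCATTGAGCAAGTTAGAGCTATCTGCCTTAGAGCCTGGGAAAAAATCCAAGACCCAGGAAGTACCTGCCCCTCATTTAATACAGTAAGACAAGGTTC
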