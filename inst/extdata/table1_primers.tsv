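locus_name	forward	reverse
16S	TCGACTGTTTACCAAAAACATAGC	ACGGAATGAACTCAAATCATGTAA
beta-actin	GCTCTTCCCCATGCCATTAT	AGCTTGAAGCAGCAGTTTGC
COI	AAGTGTATAATTGAATCACACGTTG	CTTCAGGGTGACCAAAAAATCA
ms-c25145	GGAAGAGACAGATTCCCAAT	AATGCTCTTTCCTCACAGTC
ms-AIP	CGAGACAGCGTTTTCAAG	CCACTCTTCCATTCTAACCA
ms-DMTF1	ATCGATTTAACTGCTGAAGG	AACCAAATCACAGATTTAAAATAA
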