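>IGHG1-syn1 subclass=IgG1 synthetic CH1 reference (first 107 nt)
GCCTCCACCAAGGGCCCATCGGTCTTCCCCCTGGCACCCTCCTCCAAGAGCACCTCTGGG
GGCACAGCGGCCCTGGGCTGCCTGGTCAAGGACTACTTCCCCGAACC
>IGHG1-syn2 subclass=IgG1 synthetic allele, identical across the indexed section
GCCTCCACCAAGGGCCCATCGGTCTTCCCCCTGGCACCCTCCTCCAAGAGCACCTCTGGG
GGCACAGCGGCCCTGGGCTGCCTGGTCAAGGACTACTTCCCCGAACC
>IGHG2-syn1 subclass=IgG2 synthetic CH1 reference (first 107 nt)
GCCTCCACCAAGGGCCCATCGGTCTTCCCCCTGGCGCCCTGCTCCAGGAGCACCTCCGAG
AGCACAGCGGCCCTGGGCTGCCTGGTCAAGGACTACTTCCCCGAACC
>IGHG3-syn1 subclass=IgG3 synthetic CH1 reference (first 107 nt)
GCTTCCACCAAGGGCCCATCGGTCTTCCCCCTGGCGCCCTGCTCCAGGAGCACCTCTGGG
GGCACAGCGGCCCTGGGCTGCCTGGTCAAGGACTACTTCCCCGAACC
>IGHG4-syn1 subclass=IgG4 synthetic CH1 reference (first 107 nt)
GCTTCCACCAAGGGCCCATCGGTCTTCCCCCTGGCGCCCTGCTCCAGGAGCACCTCCGAG
AGCACAGCGGCCCTGGGCTGCCTGGTCAAGGACTACTTCCCCGAACC
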