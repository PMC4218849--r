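# contaminant_index: TCTTTCCC
# i2_max_mismatch: 1
sample	index
donor_prep1	TATAGCCT
donor_prep2	ATAGAGGC
donor_prep3	CCTATCCT
donor_prep4	GGCTCTGA
patient_wk213	AGGCGAAG
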