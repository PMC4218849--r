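# Default subclass-calling scheme, version 1.
# Derived with derive_scheme() from the packaged CH1 reference alignment:
# the 12-nt window immediately 3' of the indexing-primer anchor
# (CCATCGGTCTTCCCCCTGGCRCCCTSCTCC). The klMA identifier is supplied
# explicitly (position-wise complement of the IgG1 identifier).
identifier_length: 12
identifiers:
  IgG1:
  - AAGAGCACCTCT
  IgG3:
  - AGGAGCACCTCT
  IgG24:
  - AGGAGCACCTCC
  klMA:
  - TTCTCGTGGAGA
igg_max_mismatch: 0
klma_max_mismatch: 1
discriminator:
  read: 2
  position: 4
  base_map:
    G: IgG2
    A: IgG4
  fallback: undetermined
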