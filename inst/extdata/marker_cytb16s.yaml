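forward_primer: TACCATGAGGACAAATATCATTTTGA
reverse_primer: AAGGGACGATAAGACCCTATAAAAC
offsets:
- 28
- 41
- 55
- 68
- 82
cotton_pattern: TAATT
cucumber_pattern: CGGCC
max_primer_mismatches: 2
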