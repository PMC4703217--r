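>synthetic_cotton_ref cotton-biotype pattern T,A,A,T,T at marker offsets (synthetic fragment, not derived from any sequenced mitogenome)
TACCATGAGGACAAATATCATTTTGATGATCTCTCGAATGTGCTTTCTCATATTGGCCTCGCGTCCAGAG
TTACCTGATCATATCTCACGCCATTCTAGGACACCGATGATCCGTGAGTAGGGCCATCTAGGCACAATGG
TGTGATGTTAGGTATTTAGTGCGCACTATTTTATGGTTTTATAGGGTCTTATCGTCCCTT
>synthetic_cucumber_ref cucumber-biotype pattern C,G,G,C,C at marker offsets (synthetic fragment, not derived from any sequenced mitogenome)
TACCATGAGGACAAATATCATTTTGAGGAAGCACAAGCGTGATTAACATCGGCCCCTACAGGAGTCGTTT
TTTGGGCATGGGAGGACCCCCTTCACGCGCTCGCAGTCAGAGTTGTGCTACAGCCTGATGTCTGGCGGAA
CACAAATGACTGATGGACATCTGCGGTACCGGGGAGTTTTATAGGGTCTTATCGTCCCTT
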