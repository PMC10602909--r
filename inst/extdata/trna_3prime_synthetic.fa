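>Pro synthetic tRNA cDNA; 3' 18-mer is the reverse complement of the PBS-Pro consensus
GGCTCGTTGGTCTAGGGGTATGATTCTCGCTTAGGAATCCCGGACGAGCCCCCA
>Lys synthetic tRNA cDNA; 3' 18-mer matches the tRNA-Lys3 3' end
GCCCGGATAGCTCAGTCGGTAGAGCATCAGACGTCCCTGTTCGGGCGCCA
>Leu synthetic decoy type; PBS differs from PBS-Pro in the first nine nt
GGTAGCGTGGCCGAGCGGTCTAAGGCGCTGGAATCTAGGTTACGGCACCA
>Phe synthetic decoy type; PBS differs from PBS-Pro in the first nine nt
GCCGAAATAGCTCAGTTGGGAGAGCGTTAGAAGCCTAGACTCGTTGCCA
>Trp synthetic decoy type; PBS differs from PBS-Pro in the first nine nt
GACCTCGTGGCGCAACGGTAGCGCGTCTGAGTCCTCGAACTGTCGCCA
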