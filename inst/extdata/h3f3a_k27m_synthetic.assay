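# Synthetic K27M-style LAMP assay (primer orientation, as ordered from a vendor).
# The amplicon reference is SYNTHETIC: real-style primer sequences laid end-to-end
# with an invented 31 bp spacer carrying the A>T hotspot. Matches example_assay().
name: h3f3a_k27m_synthetic
orientation: primer
target_ref: GTTTGGTAGTTGCATATGGTGATGCTGGTAGGTAAGTAAGGATACAAAGCAGACTGCCCGCGGTAAACTCGCCACGAGCGGAGCTTCACCTGCGACCGGTGGTAAAGCACCCTCTACTGGAGGGGTGGAAACCTCATCGTTACAGGTAT
hotspot: 76
wildtype: A
mutant: T
linker: TTTT
F3: GTTTGGTAGTTGCATATGGTG
B3: ATACCTGTAACGATGAGGTTTC
FIP: GCGGGCAGTCTGCTTTGTATTTTATGCTGGTAGGTAAGTAAGGA
BIP: CGACCGGTGGTAAAGCACCTTTTCACCCCTCCAGTAGAG
FLP: CGAGCCATGGTACAGAGAC
BLP: CAGGAAGCAACTGGCTACA
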