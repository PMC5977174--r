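# Synthetic optimal-codon list (21 codons) for tests and examples.
# This is a placeholder set with the size and shape of a real
# species-specific preferred-codon table; it is NOT an empirically
# determined list for any species.
TTC
CTC
ATC
GTG
TCC
TCT
CCA
ACC
GCT
GCA
TAC
CAC
CAG
AAC
AAG
GAC
GAG
TGC
AGG
GGA
GGT
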