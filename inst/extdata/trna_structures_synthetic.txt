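# Synthetic cloverleaf structure fixtures (constructed, not database-derived).
# Three-line records: >id / sequence / per-position annotation.
# Alphabet: A/a D/d C/c T/t stem sides, b D-loop, n AC-loop, * anticodon,
# u T-loop, v variable loop, s spacer, @ discriminator.
# trnK and trnL(UUR) are canonical cloverleaves; K2, K3 and L2 carry the
# anomalies characteristic of mitochondrial tRNA-like elements: K2 lacks the
# T-arm, has a purine 5' of the anticodon and a mispair at the AA-stem base;
# K3 lacks the D/AC spacer and has a mispaired AA-stem base; L2 has three
# mispairs in the AA stem.
>trnK
GGAGCTCTAAGGCTTAAGGTTGCCTAGCTCACTTTTAATGAGCTAGTGGTTCTTCAAATGAACCGAGCTCCA
AAAAAAAssDDDDbbbbbbbbddddsCCCCCnn***nncccccvvvvTTTTTuuuuuuutttttaaaaaaa@
>trnL(UUR)
GCGGATTTGGCTCATTAAAGTGAGCGCTGGACTTAAGATCCAGATCAGCTTCTTCGAATGAAGCAATCCGCA
AAAAAAAssDDDDbbbbbbbbddddsCCCCCnn***nncccccvvvvTTTTTuuuuuuutttttaaaaaaa@
>K2
GGAGCTCTAAGGCTTAAGGTTGCCTAGCTCACATTTAATGAGCTAGAGCTCAA
AAAAAAAssDDDDbbbbbbbbddddsCCCCCnn***nncccccvvaaaaaaa@
>K3
GGAGCTCTAAGGCTTAAGGTTGCCTGCTCACTTTTAATGAGCTAGTGGTTCTTCAAATGAACCGAGCTCAA
AAAAAAAssDDDDbbbbbbbbddddCCCCCnn***nncccccvvvvTTTTTuuuuuuutttttaaaaaaa@
>L2
GCGGATTTGGCTCATTAAAGTGAGCGCTGGACTTAAGATCCAGATCAGCTTCTTCGAATGAAGCAATAGACA
AAAAAAAssDDDDbbbbbbbbddddsCCCCCnn***nncccccvvvvTTTTTuuuuuuutttttaaaaaaa@
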