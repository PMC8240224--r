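>DISC1_SYNTH synthetic stand-in for DISC1 isoform a; reference peptides at 1-35 and 83-91
MPGGGPQGAPAAAGGGGVSHRAGSRDCLPPAACFRAGELSQDNVTLAHQGESLVAQDTNA
GELSHQVTDNAGELSQHVAEQKARQCGLDSRSGELAQVTDNHAGELSVQTMDKAGELSHV
NQTDAGELSVHQTNDAGELSK
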