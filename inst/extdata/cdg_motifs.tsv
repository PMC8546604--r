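# Activity motifs of c-di-GMP signaling domains.
# One motif per line: name <TAB> spec. Residue classes are single letters or
# bracketed alternatives; x(n) is a spacer of exactly n residues, x(n,m) a
# ranged spacer of n to m residues inclusive.
GGDEF	D x(7) N x(8) D x(21) R x(1) [GSA] G [DE] E F
EAL	E x(55,58) N x(31) E x(1) x(1) E x(26) D x(20) K x(35) E
PILZ	R x(1) x(1) x(1) R x(20,30) [DN] x(1) [SA] x(1) x(1) G
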