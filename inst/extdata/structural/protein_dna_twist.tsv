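protein_dna_twist	2
AA	35.3
AC	32.6
AG	33.4
AT	30.5
CA	36.6
CC	33.7
CG	35.4
CT	33.4
GA	35.8
GC	34.4
GG	33.7
GT	32.6
TA	40.0
TC	35.8
TG	36.6
TT	35.3
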