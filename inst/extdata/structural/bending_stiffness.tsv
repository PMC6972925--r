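bending_stiffness	2
AA	35
AC	60
AG	60
AT	20
CA	60
CC	130
CG	85
CT	60
GA	60
GC	85
GG	130
GT	60
TA	20
TC	60
TG	60
TT	35
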