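a_philicity	2
AA	0.1
AC	1.3
AG	0.8
AT	0.0
CA	0.7
CC	1.1
CG	1.6
CT	0.8
GA	1.1
GC	2.0
GG	1.1
GT	1.3
TA	-0.2
TC	1.1
TG	0.7
TT	0.1
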