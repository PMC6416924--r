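pam_2mer	penalty
AA	0.02
CA	0.02
GA	0.1
TA	0.02
AC	0.02
CC	0.02
GC	0.1
TC	0.02
AG	0.25
CG	0.25
GG	1
TG	0.25
AT	0.02
CT	0.02
GT	0.1
TT	0.02
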