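name	class	pattern
PR	PR	KS-AT-[DH]-KR-ACP
NR-SI	NR	SAT-KS-AT-DH-ACP-[ACP]-HTH-CMeT-[TE|ADH|NAD]-[PeptidaseS9]
NR-SII	NR	SAT-KS-AT-DH-ACP-[ACP]-[HTH]-CMeT-[ADH|NAD]-[PeptidaseS9]
NR-IX	NR	SAT-KS-AT-DH-ACP-[ACP]-[HTH]-CMeT-ADH-[PeptidaseS9]
R	R	KS-AT-DH-[CMeT]-ER-KR-[ACP]
R-V	R	KS-AT-DH-ER-KR-[KR]-ACP
R-IX	R	KS-AT-DH-[CMeT]-ER-KR-[ACP]-[Carn]
R-X	R	KS-AT-[DH]-[ER]-KR-[ACP]
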