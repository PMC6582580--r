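species	order	status
I_scapularis	Ixodida	PRESENT
R_microplus	Ixodida	CONTAMINATION
I_ricinus	Ixodida	INCONCLUSIVE
G_occidentalis	Mesostigmata	ABSENT
V_destructor	Mesostigmata	ABSENT
V_jacobsoni	Mesostigmata	ABSENT
T_mercedesae	Mesostigmata	ABSENT
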