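property	group1	group2	group3
hydrophobicity	DEKNQR	AGHPSTY	CFILMVW
vdw_volume	ACDGPST	EILNQV	FHKMRWY
polarity	CFILMVWY	AGPST	DEHKNQR
polarizability	ADGST	CEILNPQV	FHKMRWY
charge	KR	DE	ACFGHILMNPQSTVWY
secondary_structure	AEHKLMQR	CFITVWY	DGNPS
solvent_accessibility	ACFGILVW	DEKNQR	HMPSTY
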