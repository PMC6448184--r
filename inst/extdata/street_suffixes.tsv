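full	abbr
ALLEY	ALY
AVENUE	AVE
AV	AVE
BOULEVARD	BLVD
CIRCLE	CIR
COURT	CT
CRESCENT	CRES
DRIVE	DR
EXTENSION	EXT
HIGHWAY	HWY
LANE	LN
PARKWAY	PKWY
PIKE	PIKE
PLACE	PL
PLAZA	PLZ
ROAD	RD
SQUARE	SQ
STREET	ST
STR	ST
TERRACE	TER
TRAIL	TRL
TURNPIKE	TPKE
WAY	WAY
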