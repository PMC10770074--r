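cohort	phase	stratum	group	n
AUS	discovery	EBW	CRC	30
AUS	discovery	EBW	CTR	42
AUS	discovery	lean	CRC	16
AUS	discovery	lean	CTR	21
CHI	discovery	EBW	CRC	25
CHI	discovery	EBW	CTR	10
CHI	discovery	lean	CRC	48
CHI	discovery	lean	CTR	44
FRA	discovery	EBW	CRC	54
FRA	discovery	EBW	CTR	32
FRA	discovery	lean	CRC	35
FRA	discovery	lean	CTR	32
GER	discovery	EBW	CRC	12
GER	discovery	EBW	CTR	27
GER	discovery	lean	CRC	10
GER	discovery	lean	CTR	33
ITA	discovery	EBW	CRC	14
ITA	discovery	EBW	CTR	12
ITA	discovery	lean	CRC	14
ITA	discovery	lean	CTR	10
CHI_CQ	validation	EBW	CRC	28
CHI_CQ	validation	EBW	CTR	18
CHI_CQ	validation	lean	CRC	70
CHI_CQ	validation	lean	CTR	77
CHI_SH	validation	EBW	CRC	24
CHI_SH	validation	EBW	CTR	18
CHI_SH	validation	lean	CRC	56
CHI_SH	validation	lean	CTR	68
USA	validation	EBW	CRC	22
USA	validation	EBW	CTR	20
USA	validation	lean	CRC	27
USA	validation	lean	CTR	32
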