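# Mapping of external domain names/accessions to canonical domain types.
# Two tab-separated columns: alias <TAB> type (GGDEF, EAL or PILZ).
# Matching is case-insensitive; unknown names become OTHER.
GGDEF	GGDEF
PF00990	GGDEF
cd01949	GGDEF
EAL	EAL
PF00563	EAL
cd01948	EAL
PilZ	PILZ
PF07238	PILZ
cd14591	PILZ
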