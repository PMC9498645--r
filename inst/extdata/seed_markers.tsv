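# Default seed marker configuration: established subtype-specific genes
# used as starting points for guilt-by-association expansion.
gene	subtype
KRT5	basal
CDH3	basal
ID4	basal
FABP7	basal
KRT17	basal
TRIM29	basal
LAMC2	basal
ITGB4	basal
ESR1	luminal
ESR2	luminal
PGR	luminal
CCND1	luminal
FOXA1	luminal
GATA3	luminal
KRT18	luminal
KRT8	luminal
LAPTM4B	luminal
SLC39A6	luminal
SQLE	luminal
TFF3	luminal
XBP1	luminal
ERBB2	her2
GRB7	her2
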