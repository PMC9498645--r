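# Curated validated secreted marker predictions: gene symbol, UniProt
# accession, representative HG-U133A probe set, subtype prediction flags
# (basal / luminal / her2) and direction of significant paired
# tumor-vs-normal differential expression.
gene	uniprot	probe	basal	luminal	her2	direction
BGN	P21810	201262_s_at	TRUE	FALSE	FALSE	up
CEMIP	Q8WUJ3	212942_s_at	TRUE	FALSE	FALSE	up
CXCL10	P02778	204533_at	TRUE	FALSE	FALSE	up
CXCL8	P10145	211506_s_at	TRUE	FALSE	FALSE	up
HPSE	Q9Y251	219403_s_at	TRUE	FALSE	FALSE	up
INHBA	P08476	204926_at	TRUE	FALSE	FALSE	up
MMP1	P03956	204475_at	TRUE	FALSE	FALSE	up
MMP11	P24347	203878_s_at	TRUE	FALSE	FALSE	up
MMP12	P39900	204580_at	TRUE	FALSE	FALSE	up
MMP13	P45452	205959_at	TRUE	FALSE	FALSE	up
MMP9	P14780	203936_s_at	TRUE	FALSE	FALSE	up
PLAU	P00749	205479_s_at	TRUE	FALSE	FALSE	up
PLAUR	Q03405	214866_at	TRUE	FALSE	FALSE	up
FN1	P02751	214702_at	TRUE	FALSE	TRUE	up
VEGFA	P15692	210512_s_at	TRUE	TRUE	TRUE	up
COL1A2	P08123	202404_s_at	TRUE	TRUE	FALSE	up
CTSD	P07339	200766_at	FALSE	TRUE	FALSE	up
EDEM2	Q9BV94	218282_at	FALSE	TRUE	FALSE	up
HSPA5	P11021	211936_at	FALSE	TRUE	FALSE	up
IFNG	P01579	210354_at	FALSE	TRUE	FALSE	up
IL18BP	O95998	219323_s_at	FALSE	TRUE	FALSE	up
ADAMTS1	Q9UHI8	222162_s_at	TRUE	FALSE	FALSE	down
BMP2	P12643	205289_at	TRUE	FALSE	FALSE	down
BMP4	P12644	211518_s_at	TRUE	FALSE	FALSE	down
CHRDL1	Q9BU40	209763_at	TRUE	FALSE	FALSE	down
CTGF	P29279	209101_at	TRUE	FALSE	FALSE	down
CYR61	O00622	201289_at	TRUE	FALSE	FALSE	down
DCN	P07585	209335_at	TRUE	FALSE	FALSE	down
EDN1	P05305	218995_s_at	TRUE	FALSE	FALSE	down
FBLN1	P23142	201787_at	TRUE	FALSE	FALSE	down
FIGF	O43915	206742_at	TRUE	FALSE	FALSE	down
FST	P19883	207345_at	TRUE	FALSE	FALSE	down
IGF1	P05019	209540_at	TRUE	FALSE	FALSE	down
IGFBP3	P17936	210095_s_at	TRUE	FALSE	FALSE	down
LAMC2	Q13753	202267_at	TRUE	FALSE	FALSE	down
LEP	P41159	207092_at	TRUE	FALSE	FALSE	down
LPL	P06858	203549_s_at	TRUE	FALSE	FALSE	down
LTF	P02788	202018_s_at	TRUE	FALSE	FALSE	down
LUM	P51884	201744_s_at	TRUE	FALSE	FALSE	down
MFGE8	Q08431	210605_s_at	TRUE	FALSE	FALSE	down
NID1	P14543	202007_at	TRUE	FALSE	FALSE	down
OGN	P20774	218730_s_at	TRUE	FALSE	FALSE	down
PDGFD	Q9GZP0	219304_s_at	TRUE	FALSE	FALSE	down
PENK	P01210	213791_at	TRUE	FALSE	FALSE	down
PROS1	P07225	207808_s_at	TRUE	FALSE	FALSE	down
PTGDS	P41222	211663_x_at	TRUE	FALSE	FALSE	down
PTGS2	P35354	204748_at	TRUE	FALSE	FALSE	down
RELN	P78509	205923_at	TRUE	FALSE	FALSE	down
SOD3	P08294	205236_x_at	TRUE	FALSE	FALSE	down
PDGFA	P04085	205463_s_at	TRUE	TRUE	FALSE	down
ANG	P03950	205141_at	FALSE	TRUE	FALSE	down
C1S	P09871	208747_s_at	FALSE	TRUE	FALSE	down
CD59	P13987	212463_at	FALSE	TRUE	FALSE	down
KLK1	P06870	216699_s_at	FALSE	TRUE	FALSE	down
PTHLH	P12272	210355_at	FALSE	TRUE	FALSE	down
SLPI	P03973	203021_at	FALSE	TRUE	FALSE	down
SPARCL1	Q14515	200795_at	FALSE	TRUE	FALSE	down
TIMP3	P35625	201150_s_at	FALSE	TRUE	FALSE	down
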