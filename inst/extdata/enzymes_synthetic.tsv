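# Synthetic stand-in for a commercial restriction-enzyme catalogue.
# Recognition sequences and cut positions are the published ones for these
# enzymes; supplier codes and per-unit prices are illustrative only.
# name	site	suppliers	price
EcoRI	G^AATTC	BNR	62
BamHI	G^GATCC	BNR	62
HindIII	A^AGCTT	BNR	58
AluI	AG^CT	N	65
HaeIII	GG^CC	BN	60
TaqI	T^CGA	NR	64
HinfI	G^ANTC	N	62
DdeI	C^TNAG	N	68
RsaI	GT^AC	N	65
MseI	T^TAA	N	188
MboI	^GATC	N	65
NlaIII	CATG^	N	130
PstI	CTGCA^G	BNR	61
KpnI	GGTAC^C	BNR	62
SacI	GAGCT^C	BN	62
SmaI	CCC^GGG	BNR	58
XbaI	T^CTAGA	BNR	65
SpeI	A^CTAGT	BN	76
NcoI	C^CATGG	BN	72
NdeI	CA^TATG	BN	78
SspI	AAT^ATT	N	68
DraI	TTT^AAA	BN	59
AvaI	C^YCGRG	N	66
BstNI	CC^WGG	N	65
ApoI	R^AATTY	N	70
AccI	GT^MKAC	N	66
HpyCH4V	TG^CA	N	73
Tsp509I	^AATT	N	82
BfaI	C^TAG	N	88
Hpy188I	TCN^GA	N	84
BsaI	GGTCTC(1/5)	N	75
MlyI	GAGTC(5/5)	N	92
BpmI	CTGGAG(16/14)	N	98
EcoRV	GAT^ATC	BNR	61
ScrFI	CC^NGG	N	-
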