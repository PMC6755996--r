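gene	binding_site
ABCC5	species_specific
CSNK1G1	conserved
GDF15	species_specific
MRPL39	conserved
PRKD2	species_specific
TMBIM1	species_specific
ACER2	species_specific
DDR1	species_specific
GRHL3	species_specific
NINJ1	species_specific
RAP2B	conserved
TMEM63B	conserved
AEN	conserved
DGKA	conserved
GSS	conserved
NOTCH1	conserved
RASL11A	species_specific
TP53	conserved
ALDH4A1	species_specific
DYRK3	conserved
HAGH	species_specific
NTN4	conserved
RHOD	species_specific
TP53INP1	conserved
APAF1	conserved
EDA2R	conserved
HEXIM1	species_specific
PARD6G	conserved
RIN1	conserved
TRAF4	conserved
ATP6V1H	species_specific
EI24	conserved
HRAS	conserved
PERP	species_specific
RIN2	species_specific
TRIAP1	conserved
BAX	conserved
ELL	conserved
IKBIP	conserved
PHLDA3	conserved
RPS27L	conserved
TRIM32	conserved
BBC3	conserved
EPHA2	conserved
ITPKC	conserved
PIDD1	conserved
SAC3D1	conserved
TSKU	conserved
BLOC1S2	conserved
EPHX1	species_specific
KCTD11	species_specific
PLAU	species_specific
SESN2	conserved
ZMAT3	conserved
BMP7	conserved
FAM212B	conserved
KLHDC7A	conserved
PLK2	conserved
SLC12A4	conserved
ZNF219	conserved
BTG2	conserved
FAS	species_specific
LIF	conserved
PLTP	conserved
SLC4A11	species_specific
ZNF385A	species_specific
CCNG1	conserved
FBXW7	conserved
LTBP2	species_specific
PLXNB2	conserved
SPRYD4	species_specific
CDKN1A	conserved
FDXR	conserved
MDM2	conserved
PMAIP1	conserved
SULF2	conserved
CHST14	conserved
FITM2	conserved
MFGE8	species_specific
PML	species_specific
SUSD6	conserved
CPEB2	conserved
FRMD8	species_specific
MRI1	species_specific
PPM1D	conserved
SYTL1	conserved
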