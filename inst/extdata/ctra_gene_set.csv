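symbol,sign,category
IL1A,1,proinflammatory
IL1B,1,proinflammatory
IL6,1,proinflammatory
IL8,1,proinflammatory
TNF,1,proinflammatory
PTGS1,1,proinflammatory
PTGS2,1,proinflammatory
FOS,1,proinflammatory
FOSB,1,proinflammatory
FOSL1,1,proinflammatory
FOSL2,1,proinflammatory
JUN,1,proinflammatory
JUNB,1,proinflammatory
JUND,1,proinflammatory
NFKB1,1,proinflammatory
NFKB2,1,proinflammatory
REL,1,proinflammatory
RELA,1,proinflammatory
RELB,1,proinflammatory
GBP1,-1,interferon
IFI16,-1,interferon
IFI27,-1,interferon
IFI27L1,-1,interferon
IFI27L2,-1,interferon
IFI30,-1,interferon
IFI35,-1,interferon
IFI44,-1,interferon
IFI44L,-1,interferon
IFI6,-1,interferon
IFIH1,-1,interferon
IFIT1,-1,interferon
IFIT1L,-1,interferon
IFIT2,-1,interferon
IFIT3,-1,interferon
IFIT5,-1,interferon
IFITM1,-1,interferon
IFITM2,-1,interferon
IFITM3,-1,interferon
IFITM4P,-1,interferon
IFITM5,-1,interferon
IFNB1,-1,interferon
IRF2,-1,interferon
IRF7,-1,interferon
IRF8,-1,interferon
MX1,-1,interferon
MX2,-1,interferon
OAS1,-1,interferon
OAS2,-1,interferon
OAS3,-1,interferon
OASL,-1,interferon
IGJ,-1,antibody
IGLL1,-1,antibody
IGLL3,-1,antibody
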