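receptor,motif,phosphatase,sh2,kd_uM,source
PD-1,ITIM,SHP2,nSH2,0.38,printed
PD-1,ITSM,SHP2,nSH2,0.14,printed
PD-1,ITIM,SHP2,cSH2,1.4,printed
PD-1,ITSM,SHP2,cSH2,0.10,printed
PD-1,ITIM,SHP1,nSH2,0.27,printed
PD-1,ITSM,SHP1,nSH2,0.083,printed
PD-1,ITIM,SHP1,cSH2,ND,printed
PD-1,ITSM,SHP1,cSH2,1.7,printed
BTLA,ITIM,SHP1,nSH2,0.064,printed
BTLA,ITSM,SHP1,cSH2,0.86,printed
BTLA,ITSM,SHP1,nSH2,0.40,synthetic
BTLA,ITIM,SHP1,cSH2,3.0,synthetic
BTLA,ITIM,SHP2,nSH2,0.15,synthetic
BTLA,ITSM,SHP2,nSH2,0.45,synthetic
BTLA,ITIM,SHP2,cSH2,1.5,synthetic
BTLA,ITSM,SHP2,cSH2,0.20,synthetic
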