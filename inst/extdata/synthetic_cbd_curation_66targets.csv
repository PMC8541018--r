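target,activity,unit,measure,mode,source
PPARG,100,nM,EC50,full agonist,synthetic
CNR2,34,nM,Ki,partial agonist,synthetic
GPR55,445,nM,IC50,antagonist,synthetic
TRPV1,1000,nM,EC50,full agonist,synthetic
HTR3A,329,nM,IC50,negative allosteric modulator,synthetic
TRPA1,110,nM,EC50,full agonist,synthetic
TRPV4,800,nM,EC50,full agonist,synthetic
GABRA5,1400,nM,EC50,positive allosteric modulator,synthetic
TRPM8,60,nM,IC50,antagonist,synthetic
FAAH,1520,nM,IC50,inhibitor,synthetic
CNR1,1458,nM,Ki,antagonist,synthetic
GPR18,750,nM,EC50,full agonist,synthetic
TRPV2,1250,nM,EC50,full agonist,synthetic
ADORA1,580,nM,Ki,other,synthetic
HTR1A,1100,nM,Ki,other,synthetic
GLRA1,1440,nM,EC50,positive allosteric modulator,synthetic
GLRA3,1320,nM,EC50,positive allosteric modulator,synthetic
OPRM1,940,nM,Ki,negative allosteric modulator,synthetic
AQP1,430,nM,IC50,inhibitor,synthetic
VDAC1,280,nM,IC50,inhibitor,synthetic
SLC29A1,240,nM,IC50,inhibitor,synthetic
CACNA1H,820,nM,IC50,inhibitor,synthetic
ALOX5,1730,nM,IC50,inhibitor,synthetic
CHRNA7,1100,nM,IC50,antagonist,synthetic
GPR3,1060,nM,EC50,other,synthetic
GPR12,1800,nM,EC50,other,synthetic
NAAA,1900,nM,IC50,inhibitor,synthetic
SIGMAR1,1660,nM,Ki,antagonist,synthetic
TRPM2,1260,nM,EC50,full agonist,synthetic
PPARA,1550,nM,EC50,partial agonist,synthetic
ADORA2A,2.4,uM,Ki,other,synthetic
HTR2A,3.2,uM,Ki,partial agonist,synthetic
DRD2,4.1,uM,Ki,partial agonist,synthetic
OPRD1,5.5,uM,Ki,negative allosteric modulator,synthetic
SCN9A,7.8,uM,IC50,inhibitor,synthetic
ALOX15,2.56,uM,IC50,inhibitor,synthetic
PTGS1,6,uM,IC50,inhibitor,synthetic
PTGS2,9.1,uM,IC50,inhibitor,synthetic
CYP1A1,3.4,uM,IC50,inhibitor,synthetic
CYP2C9,2.7,uM,IC50,inhibitor,synthetic
CYP3A4,11,uM,IC50,inhibitor,synthetic
ABCB1,8,uM,IC50,inhibitor,synthetic
ABCG2,12,uM,IC50,inhibitor,synthetic
MGLL,27,uM,IC50,inhibitor,synthetic
DAGLA,64,uM,IC50,inhibitor,synthetic
SLC6A4,4.9,uM,IC50,inhibitor,synthetic
MAOA,15,uM,IC50,inhibitor,synthetic
ACHE,21,uM,IC50,inhibitor,synthetic
BCHE,22,uM,IC50,inhibitor,synthetic
CA2,2.2,uM,Ki,inhibitor,synthetic
TNF,30,uM,IC50,inhibitor,synthetic
IDO1,14,uM,IC50,inhibitor,synthetic
ADRA1A,6.3,uM,Ki,other,synthetic
ADRA2A,7.2,uM,Ki,other,synthetic
NR1I2,12.5,uM,EC50,full agonist,synthetic
SLC6A3,5.2,uM,IC50,inhibitor,synthetic
HTR3B,2.05,uM,IC50,negative allosteric modulator,synthetic
GLRA2,2.9,uM,EC50,positive allosteric modulator,synthetic
COMT,40,uM,IC50,inhibitor,synthetic
CYP2D6,2.4,uM,IC50,inhibitor,synthetic
ENPP1,18,uM,IC50,inhibitor,synthetic
ABHD6,9.8,uM,IC50,inhibitor,synthetic
PLA2G1B,25,uM,IC50,inhibitor,synthetic
KCNJ3,45,uM,IC50,antagonist,synthetic
GPR6,2.1,uM,EC50,other,synthetic
CHRM1,33,uM,Ki,antagonist,synthetic
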