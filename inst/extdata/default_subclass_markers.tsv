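subclass	markers	min_count
PTHLH/MOXD1	PTHLH,MOXD1	2
PTHLH	PTHLH,OPN3	2
TAC3/SEMA3A	TAC3,SEMA3A	2
TAC3	TAC3,PTPRK	2
CCK/VIP/CXCL14	CCK,VIP,CXCL14	2
CCK/VIP	CCK,VIP	2
CCK/CHST9	CCK,CHST9	2
CCK	ADARB2,CCK	2
PVALB/GRIK3	PVALB,GRIK3	2
PVALB	PVALB	3
SST/GRIK3	SST,GRIK3	2
SST/NPY/DACH1	SST,NPY,DACH1	2
SST/NPY	SST,NPY	2
CHAT	CHAT,SLC5A7	2
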