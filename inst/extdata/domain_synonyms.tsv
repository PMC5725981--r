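canonical	aliases
SET	PF00856,SET_domain
PreSET	Pre-SET,Pre_SET,preSET
PostSET	Post-SET,Post_SET,postSET
AWS	PF17907,AWS_domain
PHD	PHD1,PHD_SF,Ephd,PHD_NSD,PHD-finger
PWWP	PF00855
FYR	FYRN,FYRC,FYRN_C
ZnF_C2H2	zf-C2H2,znf_C2H2,ZnF-C2H2,C2H2
ZnF	zf,Zn_finger
ZnF_CW	zf-CW,Zf-CW
ZnF_MYND	zf-MYND,Zf-MYND
SRA	SAD_SRA,SRA_SET,YDG,YDG_SRA
WIYLD	PF10440
SAND	PF01342
HMG	HMG_box,HMG-box
HMGb	HMG-b,HMGB
GYF	PF02213
HMGCOA	MM_CoA_like,HMG_CoA
SANT	PF00249
TCR	Tesmin,TSO1,Tesmin_TSO1
Vn	Vanadium_BP,VBP
CSR	PF16019
MSL	MSL_dom
ALDH_SF	ALDH-SF,ALDH
TPR	TPR_1,TPR_2,TPR_REGION,Tetratricopeptide
Rubis_subs_bind	Rubis-subs-bind,Rubisco_LSMT,Rubisco_subs
TUDOR	Tudor
Agnet	Agenet
BAH	PF01426
MBT	PF02820
AP2	PF00847
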