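gene	contrast	direction
SERPINA1	ER+_vs_normal	ns
SERPINA1	HER2+_vs_normal	down
SERPINA1	TNBC_vs_normal	down
ATP5F1B	ER+_vs_normal	down
ATP5F1B	HER2+_vs_normal	down
ATP5F1B	TNBC_vs_normal	down
CCL20	ER+_vs_normal	down
CCL20	HER2+_vs_normal	down
CCL20	TNBC_vs_normal	down
CXCL2	ER+_vs_normal	down
CXCL2	HER2+_vs_normal	down
CXCL2	TNBC_vs_normal	down
PI3	ER+_vs_normal	down
PI3	HER2+_vs_normal	down
PI3	TNBC_vs_normal	down
LCN2	ER+_vs_normal	down
LCN2	HER2+_vs_normal	ns
LCN2	TNBC_vs_normal	down
PIGR	ER+_vs_normal	down
PIGR	HER2+_vs_normal	ns
PIGR	TNBC_vs_normal	down
DEFB1	ER+_vs_normal	down
DEFB1	HER2+_vs_normal	down
DEFB1	TNBC_vs_normal	ns
CXCL3	ER+_vs_normal	down
CXCL3	HER2+_vs_normal	down
CXCL3	TNBC_vs_normal	ns
CXCL1	ER+_vs_normal	down
CXCL1	HER2+_vs_normal	down
CXCL1	TNBC_vs_normal	ns
ISG20	ER+_vs_normal	down
ISG20	HER2+_vs_normal	down
ISG20	TNBC_vs_normal	ns
LTF	ER+_vs_normal	ns
LTF	HER2+_vs_normal	down
LTF	TNBC_vs_normal	ns
CXCL6	ER+_vs_normal	down
CXCL6	HER2+_vs_normal	ns
CXCL6	TNBC_vs_normal	ns
CXCL8	ER+_vs_normal	down
CXCL8	HER2+_vs_normal	ns
CXCL8	TNBC_vs_normal	ns
AZGP1	ER+_vs_normal	up
AZGP1	HER2+_vs_normal	down
AZGP1	TNBC_vs_normal	down
CLU	ER+_vs_normal	up
CLU	HER2+_vs_normal	down
CLU	TNBC_vs_normal	ns
H2AFJ	ER+_vs_normal	ns
H2AFJ	HER2+_vs_normal	up
H2AFJ	TNBC_vs_normal	ns
CXCL13	ER+_vs_normal	up
CXCL13	HER2+_vs_normal	ns
CXCL13	TNBC_vs_normal	ns
SCGB2A1	ER+_vs_normal	up
SCGB2A1	HER2+_vs_normal	ns
SCGB2A1	TNBC_vs_normal	ns
ZG16B	ER+_vs_normal	up
ZG16B	HER2+_vs_normal	ns
ZG16B	TNBC_vs_normal	ns
SLPI	ER+_vs_normal	ns
SLPI	HER2+_vs_normal	up
SLPI	TNBC_vs_normal	ns
BST2	ER+_vs_normal	up
BST2	HER2+_vs_normal	up
BST2	TNBC_vs_normal	up
GAPDH	ER+_vs_normal	ns
GAPDH	HER2+_vs_normal	up
GAPDH	TNBC_vs_normal	up
HMGN2	ER+_vs_normal	up
HMGN2	HER2+_vs_normal	up
HMGN2	TNBC_vs_normal	up
S100A7	ER+_vs_normal	ns
S100A7	HER2+_vs_normal	up
S100A7	TNBC_vs_normal	up
HMGB1	ER+_vs_normal	ns
HMGB1	HER2+_vs_normal	ns
HMGB1	TNBC_vs_normal	up
S100A8	ER+_vs_normal	down
S100A8	HER2+_vs_normal	ns
S100A8	TNBC_vs_normal	ns
S100A9	ER+_vs_normal	down
S100A9	HER2+_vs_normal	ns
S100A9	TNBC_vs_normal	up
B2M	ER+_vs_normal	ns
B2M	HER2+_vs_normal	ns
B2M	TNBC_vs_normal	up
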