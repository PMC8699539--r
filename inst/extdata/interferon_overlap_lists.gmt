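IRPS_overlap	IRFMS genes shared with the palbociclib (CDK4/6 inhibitor) resistance signature	IFI44	IFI27	IFIT1	IFIT3	OASL	IFI35	STAT1	HERC6	IRF7	SAMD9	SP110	IFIH1	PARP9	ISG15	PARP12	IRF9	OAS2	DDX60
IRDS_overlap	IRFMS genes shared with the DNA-damage resistance signature	IFI44	IFI27	IFIT1	IFIT3	OASL	IFI35	STAT1	HERC6	IRF7	OAS1	OAS3	BST2
RadTam_overlap	IRFMS genes shared with the radiation/tamoxifen resistance signature	IFI44	IFI27	IFIT1	IFIT3	OAS1	OAS3	BST2	OAS2	DDX60
IRFMS_printed	Printed members of the 43-gene interferon-related resistance signature (22 further members are supplement-only)	IFI44	IFI27	IFIT1	IFIT3	OASL	IFI35	STAT1	HERC6	IRF7	SAMD9	SP110	IFIH1	PARP9	ISG15	PARP12	IRF9	OAS2	DDX60	OAS1	OAS3	BST2
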