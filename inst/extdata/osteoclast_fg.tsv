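# Osteoclast-differentiation functional groups: 14 curated marker-gene groups
# (134 gene entries; genes may belong to several groups) with their expected
# state per comparison context (OCU = differentiation up, OCD = down).
group	gene	OCU	OCD
Autoregulatory - up	CCL9	Activation	Inhibition
Autoregulatory - up	CCR1	Activation	Inhibition
Autoregulatory - up	CD109	Activation	Inhibition
Autoregulatory - up	CXCL10	Activation	Inhibition
Autoregulatory - up	SDC1	Activation	Inhibition
Autoregulatory - up	VEGFC	Activation	Inhibition
Cell Differentiation signaling factors - down	PLCB4	Activation	Inhibition
Cell Differentiation signaling factors - down	PLCB2	Activation	Inhibition
Cell Differentiation signaling factors - down	GIT1	Activation	Inhibition
Cell Differentiation signaling factors - down	DOCK5	Activation	Inhibition
Cell Differentiation signaling factors - down	TRAF1	Activation	Inhibition
Cell Differentiation signaling factors - down	TRAF6	Activation	Inhibition
Cell Differentiation	CLCN7	Activation	Inhibition
Cell Differentiation	CAR2	Activation	Inhibition
Cell Differentiation	CALCR	Activation	Inhibition
Cell Differentiation	CSF1R	Activation	Inhibition
Cell Differentiation	TREM2	Activation	Inhibition
Cell Differentiation	TNFRSF11A	Activation	Inhibition
Cell Differentiation	OSCAR	Activation	Inhibition
Cell Differentiation	OCSTAMP	Activation	Inhibition
Cell Differentiation	MST1R	Activation	Inhibition
Cell Differentiation	ITGB3	Activation	Inhibition
Cell Differentiation	DCSTAMP	Activation	Inhibition
Cytoskeleton Control	DCSTAMP	Activation	Inhibition
Cytoskeleton Control	LAD1	Activation	Inhibition
Cytoskeleton Control	MYO1B	Activation	Inhibition
Cytoskeleton Control	OCSTAMP	Activation	Inhibition
Cytoskeleton Control	SCIN	Activation	Inhibition
Cytoskeleton Control	MYOD1	Activation	Inhibition
Cytoskeleton Control	MARCKS	Activation	Inhibition
Integrin Beta3	CLCN7	Activation	Inhibition
Integrin Beta3	OCSTAMP	Activation	Inhibition
Integrin Beta3	CALCR	Activation	Inhibition
Integrin Beta3	MST1R	Activation	Inhibition
Integrin Beta3	CTSK	Activation	Inhibition
Integrin Beta3	MMP14	Activation	Inhibition
Integrin Beta3	ITGB3	Activation	Inhibition
Integrin Beta3	MYO1D	Activation	Inhibition
Integrin Beta3	ACP5	Activation	Inhibition
Integrin Beta3	MMP9	Activation	Inhibition
Integrin Beta3	CAR2	Activation	Inhibition
Integrin Beta3	OSCAR	Activation	Inhibition
Secreted Factors for External Cells - up	INF2	Activation	Inhibition
Secreted Factors for External Cells - up	SEMA4D	Activation	Inhibition
Secreted Factors for External Cells - up	SGPL1	Activation	Inhibition
Secreted Factors for External Cells - up	SPP1	Activation	Inhibition
Secreted Factors for External Cells - up	CXCL10	Activation	Inhibition
Secreted Factors for External Cells - up	CCL9	Activation	Inhibition
Coupling Factors	PGF	Activation	Inhibition
Coupling Factors	SPNS2	Activation	Inhibition
Coupling Factors	CD200	Activation	Inhibition
Coupling Factors	SGPL1	Activation	Inhibition
Coupling Factors	SEMA7A	Activation	Inhibition
Coupling Factors	LIF	Activation	Inhibition
Coupling Factors	CST7	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	VCAN	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	ATP6V0D2	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	CAR2	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	CLCN7	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	SLC9B6	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	CTSK	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	ACP5	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	PDE2A	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	MMP14	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	HTRA1	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	MMP9	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	ADAM10	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	ATP6V0B	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	ATP6V0C	Activation	Inhibition
ACID & Enzymes for Matrix Dissolution	ATP6V0C-PS2	Activation	Inhibition
Autoregulatory - down	C1QA	Inhibition	Activation
Autoregulatory - down	C1QB	Inhibition	Activation
Autoregulatory - down	C1QC	Inhibition	Activation
Autoregulatory - down	CCL2	Inhibition	Activation
Autoregulatory - down	CCL3	Inhibition	Activation
Autoregulatory - down	CCL4	Inhibition	Activation
Autoregulatory - down	CCL6	Inhibition	Activation
Autoregulatory - down	CCL7	Inhibition	Activation
Autoregulatory - down	CXCL14	Inhibition	Activation
Autoregulatory - down	IGFBP4	Inhibition	Activation
Autoregulatory - down	PF4	Inhibition	Activation
Calcinuren Pathway	CALM1	Inhibition	Activation
Calcinuren Pathway	CAMK1	Inhibition	Activation
Calcinuren Pathway	CAMK2A	Inhibition	Activation
Calcinuren Pathway	CALM2	Inhibition	Activation
Calcinuren Pathway	CALM3	Inhibition	Activation
Calcinuren Pathway	PPP3CA	Inhibition	Activation
Cell Differentiation signaling factors - up	PPP2R3A	Inhibition	Activation
Cell Differentiation signaling factors - up	PPP3CA	Inhibition	Activation
Cell Differentiation signaling factors - up	CALM2	Inhibition	Activation
Cell Differentiation signaling factors - up	PPP2R3C	Inhibition	Activation
Cell Differentiation signaling factors - up	CAMK1	Inhibition	Activation
Cell Differentiation signaling factors - up	TNFAIP2	Inhibition	Activation
Cell Differentiation signaling factors - up	CAMK2A	Inhibition	Activation
Cell Differentiation signaling factors - up	CALM3	Inhibition	Activation
Cell Differentiation signaling factors - up	CALM1	Inhibition	Activation
Cell Signaling	SLIT1	Inhibition	Activation
Cell Signaling	SGPL1	Inhibition	Activation
Cell Signaling	INFB	Inhibition	Activation
Cell Signaling	IL10	Inhibition	Activation
Cell Signaling	CXCL5	Inhibition	Activation
Cell Signaling	IGF1	Inhibition	Activation
Cell Signaling	SPP1	Inhibition	Activation
Cell Signaling	SLIT3	Inhibition	Activation
Cell Signaling	C1QA	Inhibition	Activation
Cell Signaling	CCL8	Inhibition	Activation
Cell Signaling	CCL7	Inhibition	Activation
Cell Signaling	C1QC	Inhibition	Activation
Cell Signaling	C1QB	Inhibition	Activation
MSC Signature	ACTA2	Inhibition	Activation
MSC Signature	ACTG2	Inhibition	Activation
MSC Signature	BGN	Inhibition	Activation
MSC Signature	CCND1	Inhibition	Activation
MSC Signature	COL1A1	Inhibition	Activation
MSC Signature	COL1A2	Inhibition	Activation
MSC Signature	COL2A1	Inhibition	Activation
MSC Signature	DKK3	Inhibition	Activation
MSC Signature	FN1	Inhibition	Activation
MSC Signature	SERPINH1	Inhibition	Activation
MSC Signature	SPARC	Inhibition	Activation
MSC Signature	TNC	Inhibition	Activation
Secreted Factors for External Cells - down	CCL6	Inhibition	Activation
Secreted Factors for External Cells - down	CCL4	Inhibition	Activation
Secreted Factors for External Cells - down	CCL3	Inhibition	Activation
Secreted Factors for External Cells - down	CCL2	Inhibition	Activation
Secreted Factors for External Cells - down	C1QC	Inhibition	Activation
Secreted Factors for External Cells - down	C1QB	Inhibition	Activation
Secreted Factors for External Cells - down	CCL7	Inhibition	Activation
Secreted Factors for External Cells - down	CXCL14	Inhibition	Activation
Secreted Factors for External Cells - down	CD200R1	Inhibition	Activation
Secreted Factors for External Cells - down	CXCL16	Inhibition	Activation
Secreted Factors for External Cells - down	IGF1	Inhibition	Activation
Secreted Factors for External Cells - down	APOE	Inhibition	Activation
Secreted Factors for External Cells - down	C1QA	Inhibition	Activation
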