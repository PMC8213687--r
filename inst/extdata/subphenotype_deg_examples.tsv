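gene_name	ensembl_id	cpm_ctl	cpm_case	ratio_printed	fdr	comparison
HBB	ENSG00000244734.18	81.20	421.79	5.19	0.01959	male_ctl_vs_E
SELL	ENSG00000188404.4	5.02	24.15	4.81	0.00001	male_ctl_vs_E
IGHA1	ENSG00000211895.3	8.67	25.44	2.93	0.00773	male_ctl_vs_E
S100A8	ENSG00000143546.5	20.73	56.03	2.70	0.00014	male_ctl_vs_E
CSF3R	ENSG00000119535.13	7.74	24.45	3.16	0.02079	male_ctl_vs_E
GPR97	ENSG00000182885.10	2.56	13.31	5.20	0.02805	male_ctl_vs_E
ITGAX	ENSG00000140678.12	9.44	25.17	2.67	0.04854	male_ctl_vs_E
HCAR3	ENSG00000255398.2	11.04	27.83	2.52	0.04379	male_ctl_vs_E
CXCL1	ENSG00000163739.4	133.36	200.97	1.51	0.00038	male_ctl_vs_E
MNDA	ENSG00000163563.7	13.53	29.91	2.21	0.04268	male_ctl_vs_E
MT-ND1	ENSG00000198888.2	8087.88	13676.81	1.69	0.00836	male_ctl_vs_E
MT-CO2	ENSG00000198712.1	9318.08	14155.29	1.52	0.04335	male_ctl_vs_E
Metazoa_SRP	ENSG00000266422.1	20.22	71.16	3.52	0.00977	male_ctl_vs_A
RN7SL1	ENSG00000258486.1	20.22	70.83	3.50	0.01000	male_ctl_vs_A
RN7SL2	ENSG00000265150.1	34.67	115.33	3.33	0.01497	male_ctl_vs_A
RNA45S5	ENSG00000225840.1	231.86	595.30	2.57	0.03197	male_ctl_vs_A
KRT13	ENSG00000171401.10	9.90	47.72	4.82	0.0045	male_ctl_vs_A
SPP1	ENSG00000118785.9	16.42	45.83	2.79	0.0300	male_ctl_vs_A
TNC	ENSG00000041982.10	37.74	97.25	2.58	0.03118	male_ctl_vs_A
CD36	ENSG00000135218.13	10.88	36.27	3.33	0.0467	male_ctl_vs_A
F3	ENSG00000117525.9	199.98	324.69	1.62	0.01322	male_ctl_vs_A
KLF4	ENSG00000136826.9	39.39	60.44	1.53	0.0452	male_ctl_vs_A
FGFBP1	ENSG00000137440.3	11.55	44.12	3.82	1.71e-08	female_ctl_vs_E
TPSB2	ENSG00000197253.8	19.49	58.64	3.01	0.04356	female_ctl_vs_E
CDC20B	ENSG00000164287.8	26.30	68.74	2.61	0.00451	female_ctl_vs_E
ANKRD18A	ENSG00000180071.12	11.17	28.90	2.59	0.02803	female_ctl_vs_E
CPA3	ENSG00000163751.3	10.01	60.80	6.08	0.01515	female_ctl_vs_E
TPSAB1	ENSG00000172236.11	32.77	115.12	3.51	0.00134	female_ctl_vs_E
FKBP5	ENSG00000096060.9	45.85	149.93	3.27	4.32e-06	female_ctl_vs_E
SERPINB2	ENSG00000197632.4	20.44	51.94	2.54	4.28e-06	female_ctl_vs_E
BST2	ENSG00000130303.8	18.00	36.80	2.04	0.04016	female_ctl_vs_A
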