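RP	ribosomal protein genes (synthetic ids)	g0001	g0002	g0003	g0004	g0005	g0006	g0007	g0008	g0009	g0010	g0011	g0012	g0013	g0014	g0015	g0016	g0017	g0018	g0019	g0020
Ribi	ribosome biogenesis regulon (synthetic ids)	g0021	g0022	g0023	g0024	g0025	g0026	g0027	g0028	g0029	g0030	g0031	g0032	g0033	g0034	g0035	g0036	g0037	g0038	g0039	g0040
ESR_induced	environmental stress response, induced (synthetic ids)	g0041	g0042	g0043	g0044	g0045	g0046	g0047	g0048	g0049	g0050	g0051	g0052	g0053	g0054	g0055	g0056	g0057	g0058	g0059	g0060	g0061	g0062	g0063	g0064	g0065
ESR_repressed	environmental stress response, repressed (synthetic ids)	g0066	g0067	g0068	g0069	g0070	g0071	g0072	g0073	g0074	g0075	g0076	g0077	g0078	g0079	g0080	g0081	g0082	g0083	g0084	g0085	g0086	g0087	g0088	g0089	g0090
proteasome	proteasome subunits (synthetic ids)	g0091	g0092	g0093	g0094	g0095	g0096	g0097	g0098	g0099	g0100	g0101	g0102
AA_biosynthesis	GCN4-regulated amino-acid biosynthesis (synthetic ids)	g0103	g0104	g0105	g0106	g0107	g0108	g0109	g0110	g0111	g0112	g0113	g0114	g0115	g0116	g0117	g0118	g0119	g0120	g0121	g0122
GF	glycolysis and fermentation (synthetic ids)	g0123	g0124	g0125	g0126	g0127	g0128	g0129	g0130	g0131	g0132
PPP	pentose phosphate pathway (synthetic ids)	g0133	g0134	g0135	g0136	g0137	g0138	g0139	g0140
TCA	TCA cycle (synthetic ids)	g0141	g0142	g0143	g0144	g0145	g0146	g0147	g0148	g0149	g0150
RC	respiratory chain (synthetic ids)	g0151	g0152	g0153	g0154	g0155	g0156	g0157	g0158	g0159	g0160	g0161	g0162
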