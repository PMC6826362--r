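ketone_body_metabolism	synthetic pathway enriched in planted over-dominant genes	gene_1301	gene_1302	gene_1303	gene_1304	gene_1305	gene_1306	gene_1307	gene_1308	gene_1309	gene_1310	gene_1311	gene_1312	gene_1313	gene_1314	gene_1315	gene_0001	gene_0002	gene_0003	gene_0004	gene_0005
butanoate_metabolism	synthetic pathway enriched in planted over-dominant genes	gene_1316	gene_1317	gene_1318	gene_1319	gene_1320	gene_1321	gene_1322	gene_1323	gene_1324	gene_1325	gene_0006	gene_0007	gene_0008	gene_0009	gene_0010	gene_0011	gene_0012	gene_0013	gene_0014	gene_0015
branched_chain_aa_degradation	synthetic pathway with mild over-dominant overlap	gene_1326	gene_1327	gene_1328	gene_1329	gene_1330	gene_0016	gene_0017	gene_0018	gene_0019	gene_0020	gene_0021	gene_0022	gene_0023	gene_0024	gene_0025
glycolysis	synthetic background pathway	gene_0026	gene_0027	gene_0028	gene_0029	gene_0030	gene_0031	gene_0032	gene_0033	gene_0034	gene_0035	gene_0036	gene_0037	gene_0038	gene_0039	gene_0040
oxidative_phosphorylation	synthetic background pathway	gene_0041	gene_0042	gene_0043	gene_0044	gene_0045	gene_0046	gene_0047	gene_0048	gene_0049	gene_0050	gene_0051	gene_0052	gene_0053	gene_0054	gene_0055	gene_0056	gene_0057	gene_0058	gene_0059	gene_0060
ribosome_biogenesis	synthetic background pathway	gene_0061	gene_0062	gene_0063	gene_0064	gene_0065	gene_0066	gene_0067	gene_0068	gene_0069	gene_0070	gene_0071	gene_0072	gene_0073	gene_0074	gene_0075	gene_0076	gene_0077	gene_0078	gene_0079	gene_0080
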