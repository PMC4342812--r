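# 29 radiation-hypomethylated candidate genes with exclusion annotations.
# pseudogene / paralog_similarity_pct flags follow the published candidate list;
# probe_id, chromosome, tss, strand and island_relation are SYNTHETIC placeholders
# (no array accession or coordinates were deposited for the source experiment).
# Empty paralog_similarity_pct means "not assessed", not 0.
probe_id	gene_symbols	chromosome	tss	strand	island_relation	pseudogene	paralog_similarity_pct
cg90000001	ANGPT1	chr8	1080000	-	island	FALSE	
cg90000002	APBB2	chr4	1040000	-	island	FALSE	
cg90000003	ATP5A1	chr18	1180000	+	island	FALSE	
cg90000004	C10orf140	chr10	1100000	+	island	FALSE	
cg90000005	C10orf4	chr10	1101000	+	island	FALSE	
cg90000006	CASC1	chr12	1120000	+	island	FALSE	
cg90000007	CHGA	chr14	1140000	+	island	FALSE	
cg90000008	CTGF	chr6	1060000	-	island	FALSE	
cg90000009	CXADRP2	chr15	1150000	+	island	TRUE	
cg90000010	HAUS1	chr18	1181000	-	island	FALSE	
cg90000011	IFI16	chr1	1010000	+	island	FALSE	
cg90000012	IGLON5	chr19	1190000	-	island	FALSE	
cg90000013	LBR	chr1	1011000	-	island	FALSE	
cg90000014	LMAN1	chr18	1182000	-	island	FALSE	
cg90000015	LYRM5	chr12	1121000	+	island	FALSE	
cg90000016	MCOLN1	chr19	1191000	+	island	FALSE	
cg90000017	MTMR8	chrX	1230000	+	island	FALSE	
cg90000018	PDZRN3	chr3	1030000	-	island	FALSE	
cg90000019	PLCL2	chr3	1031000	+	island	FALSE	
cg90000020	PLEKHM2	chr1	1012000	+	island	FALSE	
cg90000021	RASAL1	chr12	1122000	+	island	FALSE	
cg90000022	SLC43A2	chr17	1170000	+	island	FALSE	
cg90000023	SP1	chr12	1123000	+	island	FALSE	
cg90000024	TCERG1L	chr10	1102000	-	island	FALSE	
cg90000025	TSPY1	chrY	1240000	+	island	FALSE	94
cg90000026	TSPY4	chrY	1241000	+	island	FALSE	94
cg90000027	ZNF175	chr19	1192000	+	island	FALSE	
cg90000028	ZNF69	chr19	1193000	+	island	FALSE	
cg90000029	ZSWIM5	chr1	1013000	+	island	FALSE	
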