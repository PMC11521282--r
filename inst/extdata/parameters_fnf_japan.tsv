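name	label	point	low	high	role
p_dis_sb_65_69	Probability of dislocation after SB-THA, 65-69 y	0.0240			probability
p_dis_sb_70_74	Probability of dislocation after SB-THA, 70-74 y	0.0235			probability
p_dis_sb_75_79	Probability of dislocation after SB-THA, 75-79 y	0.0215			probability
p_dis_sb_80_84	Probability of dislocation after SB-THA, 80-84 y	0.0190			probability
p_dis_sb_85_89	Probability of dislocation after SB-THA, 85-89 y	0.0132			probability
p_revdis_sb_65_69	Probability of revision dislocation after SB-THA, 65-69 y	0.0097			probability
p_revdis_sb_70_74	Probability of revision dislocation after SB-THA, 70-74 y	0.0103			probability
p_revdis_sb_75_79	Probability of revision dislocation after SB-THA, 75-79 y	0.0086			probability
p_revdis_sb_80_84	Probability of revision dislocation after SB-THA, 80-84 y	0.0067			probability
p_revdis_sb_85_89	Probability of revision dislocation after SB-THA, 85-89 y	0.0040			probability
p_revnondis_sb_65_69	Probability of revision non-dislocation after SB-THA, 65-69 y	0.0211			probability
p_revnondis_sb_70_74	Probability of revision non-dislocation after SB-THA, 70-74 y	0.0225			probability
p_revnondis_sb_75_79	Probability of revision non-dislocation after SB-THA, 75-79 y	0.0187			probability
p_revnondis_sb_80_84	Probability of revision non-dislocation after SB-THA, 80-84 y	0.0146			probability
p_revnondis_sb_85_89	Probability of revision non-dislocation after SB-THA, 85-89 y	0.0087			probability
rr_dis_dm_sb	Relative risk of dislocation, DM-THA vs SB-THA	0.17	0.04	0.79	rr
rr_dis_dm_bha	Relative risk of dislocation, DM-THA vs BHA	0.41	0.19	0.87	rr
rr_revdis_bha_dm	Relative risk of revision dislocation, BHA vs DM-THA	7.16	2.18	23.58	rr
rr_revnondis_bha_dm	Relative risk of revision non-dislocation, BHA vs DM-THA	0.87	0.40	1.88	rr
rr_revdis_dm_sb	Relative risk of revision dislocation, DM-THA vs SB-THA	0.40	0.27	0.59	rr
rr_revnondis_dm_sb	Relative risk of revision non-dislocation, DM-THA vs SB-THA	0.93	0.75	1.16	rr
du_dis	Disutility due to dislocation	-0.110	-0.153	-0.067	disutility
du_rtha	Disutility due to R-THA	-0.185	-0.258	-0.112	disutility
du_rrtha	Disutility due to RR-THA	-0.287	-0.400	-0.174	disutility
u_well_bha	Health state utility of well post-BHA	0.820	0.660	0.980	utility
u_well_sb	Health state utility of well post-SB-THA	0.870	0.720	1.000	utility
u_well_dm	Health state utility of well post-DM-THA	0.870	0.720	1.000	utility
u_well_rtha	Health state utility of well post-R-THA	0.685	0.535	0.835	utility
u_well_rrtha	Health state utility of well post-RR-THA	0.583	0.433	0.733	utility
u_dead	Health state utility of mortality	0.000	0.000	0.000	utility
c_dislocation	Costs after dislocation (yen)	220679	134173	307185	cost
c_implant_bha	Cost of BHA implants (yen)	572000	572000	572000	cost
c_implant_sb	Cost of SB-THA implants (yen)	611000	611000	611000	cost
c_implant_dm	Cost of DM-THA implants (yen)	714000	714000	714000	cost
fee_bha	Fee for medical service of BHA (yen)	195000	195000	195000	cost
fee_tha	Fee for medical service of SB/DM-THA (yen)	376900	376900	376900	cost
fee_rtha	Fee for medical service of R-THA (yen)	548100	548100	548100	cost
c_initial_bha	Initial year costs of BHA (yen)	2122628	1290558	2954698	cost
c_initial_tha	Initial year costs of THA (yen)	2191285	1332301	3050269	cost
c_well_annual	Costs of well post-surgery, annual (yen)	1399413	1052656	1746170	cost
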