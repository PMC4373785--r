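id	name	equation	reversible	gene_association	pathway
R_GLCt1r	glucose transport (blood-brain)	M_glc_DASH_D_e <-> M_glc_DASH_D_c	true	SLC2A1 or SLC2A3	transport
R_L_LACt2r	L-lactate/H+ symport	M_h_e + M_lac_DASH_L_e <-> M_h_c + M_lac_DASH_L_c	true	SLC16A1 or SLC16A7	transport
R_PYRt2r	pyruvate/H+ symport	M_h_e + M_pyr_e <-> M_h_c + M_pyr_c	true	SLC16A1	transport
R_O2t	oxygen diffusion	M_o2_e <-> M_o2_c	true		transport
R_CO2t	CO2 diffusion	M_co2_e <-> M_co2_c	true		transport
R_H2Ot	water diffusion	M_h2o_e <-> M_h2o_c	true	AQP4	transport
R_Ht	proton exchange (plasma membrane)	M_h_e <-> M_h_c	true		transport
R_HEX1	hexokinase	M_atp_c + M_glc_DASH_D_c -> M_adp_c + M_g6p_c + M_h_c	false	HK1 or HK2	glycolysis
R_PGI	glucose-6-phosphate isomerase	M_g6p_c <-> M_f6p_c	true	GPI	glycolysis
R_PFK	phosphofructokinase	M_atp_c + M_f6p_c -> M_adp_c + M_fdp_c + M_h_c	false	PFKL or PFKM or PFKP	glycolysis
R_FBA	fructose-bisphosphate aldolase	M_fdp_c <-> M_dhap_c + M_g3p_c	true	ALDOA or ALDOC	glycolysis
R_TPI	triose-phosphate isomerase	M_dhap_c <-> M_g3p_c	true	TPI1	glycolysis
R_GAPD	glyceraldehyde-3-phosphate dehydrogenase	M_g3p_c + M_nad_c + M_pi_c <-> M_13dpg_c + M_h_c + M_nadh_c	true	GAPDH	glycolysis
R_PGK	phosphoglycerate kinase	M_3pg_c + M_atp_c <-> M_13dpg_c + M_adp_c	true	PGK1	glycolysis
R_PGM	phosphoglycerate mutase	M_2pg_c <-> M_3pg_c	true	PGAM1	glycolysis
R_ENO	enolase	M_2pg_c <-> M_h2o_c + M_pep_c	true	ENO1 or ENO2	glycolysis
R_PYK	pyruvate kinase	M_adp_c + M_h_c + M_pep_c -> M_atp_c + M_pyr_c	false	PKM	glycolysis
R_LDH_L	L-lactate dehydrogenase	M_lac_DASH_L_c + M_nad_c <-> M_h_c + M_nadh_c + M_pyr_c	true	LDHA or LDHB	glycolysis
R_G6PDH2r	glucose-6-phosphate dehydrogenase	M_g6p_c + M_nadp_c <-> M_6pgl_c + M_h_c + M_nadph_c	true	G6PD	ppp
R_PGL	6-phosphogluconolactonase	M_6pgl_c + M_h2o_c -> M_6pgc_c + M_h_c	false	PGLS	ppp
R_GND	phosphogluconate dehydrogenase	M_6pgc_c + M_nadp_c -> M_co2_c + M_nadph_c + M_ru5p_DASH_D_c	false	PGD	ppp
R_RPI	ribose-5-phosphate isomerase	M_r5p_c <-> M_ru5p_DASH_D_c	true	RPIA	ppp
R_RPE	ribulose-5-phosphate epimerase	M_ru5p_DASH_D_c <-> M_xu5p_DASH_D_c	true	RPE	ppp
R_TKT1	transketolase 1	M_r5p_c + M_xu5p_DASH_D_c <-> M_g3p_c + M_s7p_c	true	TKT	ppp
R_TALA	transaldolase	M_g3p_c + M_s7p_c <-> M_e4p_c + M_f6p_c	true	TALDO1	ppp
R_TKT2	transketolase 2	M_e4p_c + M_xu5p_DASH_D_c <-> M_f6p_c + M_g3p_c	true	TKT	ppp
R_GTHOr	glutathione reductase	M_gthox_c + M_h_c + M_nadph_c -> 2 M_gthrd_c + M_nadp_c	false	GSR	ppp
R_GLUDC	glutamate decarboxylase	M_glu_DASH_L_c + M_h_c -> M_4abut_c + M_co2_c	false	GAD1 or GAD2	gaba
R_4ABUTtm	GABA mitochondrial transport	M_4abut_c <-> M_4abut_m	true	SLC25A18	gaba
R_ABTArm	4-aminobutyrate transaminase (mito)	M_4abut_m + M_akg_m -> M_glu_DASH_L_m + M_sucsal_m	false	ABAT	gaba
R_SSALxm	succinate-semialdehyde dehydrogenase (NAD, mito)	M_h2o_m + M_nad_m + M_sucsal_m -> 2 M_h_m + M_nadh_m + M_succ_m	false	ALDH5A1	gaba
R_ASPTA	aspartate transaminase	M_akg_c + M_asp_DASH_L_c <-> M_glu_DASH_L_c + M_oaa_c	true	GOT1	mas
R_ASPTAm	aspartate transaminase (mito)	M_akg_m + M_asp_DASH_L_m <-> M_glu_DASH_L_m + M_oaa_m	true	GOT2	mas
R_MDH	malate dehydrogenase	M_mal_DASH_L_c + M_nad_c <-> M_h_c + M_nadh_c + M_oaa_c	true	MDH1	mas
R_MDHm	malate dehydrogenase (mito)	M_mal_DASH_L_m + M_nad_m <-> M_h_m + M_nadh_m + M_oaa_m	true	MDH2	mas
R_AKGMAL	alpha-ketoglutarate/malate antiport	M_akg_m + M_mal_DASH_L_c <-> M_akg_c + M_mal_DASH_L_m	true	SLC25A11	mas
R_ASPGLUm	aspartate/glutamate carrier	M_asp_DASH_L_m + M_glu_DASH_L_c + M_h_c -> M_asp_DASH_L_c + M_glu_DASH_L_m + M_h_m	false	SLC25A12 or SLC25A13	mas
R_G3PD1	glycerol-3-phosphate dehydrogenase (NAD)	M_glyc3p_c + M_nad_c <-> M_dhap_c + M_h_c + M_nadh_c	true	GPD1	gps
R_G3PD2m	glycerol-3-phosphate dehydrogenase (mito, FAD)	M_glyc3p_c + M_q10_m -> M_dhap_c + M_q10h2_m	false	GPD2	gps
R_PYRt2m	pyruvate mitochondrial carrier	M_h_c + M_pyr_c -> M_h_m + M_pyr_m	false	MPC1 and MPC2	tca
R_PDHm	pyruvate dehydrogenase	M_coa_m + M_nad_m + M_pyr_m -> M_accoa_m + M_co2_m + M_nadh_m	false	PDHA1 and PDHB and DLAT and DLD	tca
R_CSm	citrate synthase	M_accoa_m + M_h2o_m + M_oaa_m -> M_cit_m + M_coa_m + M_h_m	false	CS	tca
R_ACONTm	aconitase (mito)	M_cit_m <-> M_icit_m	true	ACO2	tca
R_ICDHxm	isocitrate dehydrogenase (NAD, mito)	M_icit_m + M_nad_m -> M_akg_m + M_co2_m + M_nadh_m	false	IDH3A and IDH3B and IDH3G	tca
R_AKGDm	alpha-ketoglutarate dehydrogenase	M_akg_m + M_coa_m + M_nad_m -> M_co2_m + M_nadh_m + M_succoa_m	false	OGDH and DLST and DLD	tca
R_SUCOAS1m	succinyl-CoA synthetase (GDP)	M_gdp_m + M_pi_m + M_succoa_m <-> M_coa_m + M_gtp_m + M_succ_m	true	SUCLG1 and SUCLG2	tca
R_SUCD1m	succinate dehydrogenase	M_fad_m + M_succ_m <-> M_fadh2_m + M_fum_m	true	SDHA and SDHB	tca
R_SUCDim	succinate dehydrogenase (ubiquinone)	M_fadh2_m + M_q10_m -> M_fad_m + M_q10h2_m	false	SDHC and SDHD	tca
R_FUMm	fumarase (mito)	M_fum_m + M_h2o_m <-> M_mal_DASH_L_m	true	FH	tca
R_CITtam	citrate/malate antiport	M_cit_m + M_mal_DASH_L_c <-> M_cit_c + M_mal_DASH_L_m	true	SLC25A1	tca
R_ACONT	aconitase	M_cit_c <-> M_icit_c	true	ACO1	tca
R_ICDHy	isocitrate dehydrogenase (NADP)	M_icit_c + M_nadp_c -> M_akg_c + M_co2_c + M_nadph_c	false	IDH1	tca
R_HCO3Em	carbonic anhydrase (mito)	M_co2_m + M_h2o_m <-> M_h_m + M_hco3_m	true	CA5A	misc
R_PCm	pyruvate carboxylase	M_atp_m + M_hco3_m + M_pyr_m -> M_adp_m + M_h_m + M_oaa_m + M_pi_m	false	PC	tca
R_NADH2_u10m	NADH dehydrogenase (complex I)	5 M_h_m + M_nadh_m + M_q10_m -> 4 M_h_c + M_nad_m + M_q10h2_m	false	NDUFS1 and NDUFV1 and NDUFS2	oxphos
R_CYOR_u10m	cytochrome c reductase (complex III)	2 M_ficytC_m + 2 M_h_m + M_q10h2_m -> 2 M_focytC_m + 4 M_h_c + M_q10_m	false	UQCRC1 and UQCRC2 and CYC1	oxphos
R_CYOOm2	cytochrome c oxidase (complex IV)	4 M_focytC_m + 8 M_h_m + M_o2_m -> 4 M_ficytC_m + 4 M_h_c + 2 M_h2o_m	false	COX4I1 and COX5A and COX6C	oxphos
R_ATPS4m	ATP synthase (F0/F1)	M_adp_m + 4 M_h_c + M_pi_m -> M_atp_m + M_h2o_m + 3 M_h_m	false	ATP5A1 and ATP5B and ATP5C1	oxphos
R_NDPK1m	nucleoside-diphosphate kinase (mito)	M_atp_m + M_gdp_m <-> M_adp_m + M_gtp_m	true	NME4	oxphos
R_ATPtm	ADP/ATP translocase	M_adp_c + M_atp_m -> M_adp_m + M_atp_c	false	SLC25A4 or SLC25A5	oxphos
R_PIt2m	phosphate/H+ symport (mito)	M_h_c + M_pi_c -> M_h_m + M_pi_m	false	SLC25A3	oxphos
R_Htm	mitochondrial proton leak	M_h_c -> M_h_m	false		oxphos
R_O2tm	oxygen diffusion (mito)	M_o2_c <-> M_o2_m	true		transport
R_CO2tm	CO2 diffusion (mito)	M_co2_m <-> M_co2_c	true		transport
R_H2Otm	water diffusion (mito)	M_h2o_m <-> M_h2o_c	true		transport
R_GLNS	glutamine synthetase	M_atp_c + M_glu_DASH_L_c + M_nh4_c -> M_adp_c + M_gln_DASH_L_c + M_h_c + M_pi_c	false	GLUL	glu
R_GLUNm	glutaminase (mito)	M_gln_DASH_L_m + M_h2o_m -> M_glu_DASH_L_m + M_nh4_m	false	GLS	glu
R_GLUtm	glutamate mitochondrial carrier	M_glu_DASH_L_c <-> M_glu_DASH_L_m	true	SLC25A22	glu
R_CK	creatine kinase	M_atp_c + M_creat_c <-> M_adp_c + M_h_c + M_pcreat_c	true	CKB	misc
R_CKm	creatine kinase (mito)	M_atp_m + M_creat_m <-> M_adp_m + M_h_m + M_pcreat_m	true	CKMT1A	misc
R_DM_atp_c_	ATP demand (maintenance)	M_atp_c + M_h2o_c -> M_adp_c + M_h_c + M_pi_c	false		misc
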