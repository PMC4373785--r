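id	name	compartment	boundary
M_13dpg_c	1,3-bisphosphoglycerate [cytosol]	c	false
M_2pg_c	2-phosphoglycerate [cytosol]	c	false
M_3pg_c	3-phosphoglycerate [cytosol]	c	false
M_4abut_c	4-aminobutyrate (GABA) [cytosol]	c	false
M_4abut_m	4-aminobutyrate (GABA) [mitochondrion]	m	false
M_6pgc_c	6-phosphogluconate [cytosol]	c	false
M_6pgl_c	6-phosphoglucono-1,5-lactone [cytosol]	c	false
M_accoa_m	acetyl-CoA [mitochondrion]	m	false
M_adp_c	ADP [cytosol]	c	false
M_adp_m	ADP [mitochondrion]	m	false
M_akg_c	alpha-ketoglutarate [cytosol]	c	false
M_akg_m	alpha-ketoglutarate [mitochondrion]	m	false
M_asp_DASH_L_c	L-aspartate [cytosol]	c	false
M_asp_DASH_L_m	L-aspartate [mitochondrion]	m	false
M_atp_c	ATP [cytosol]	c	false
M_atp_m	ATP [mitochondrion]	m	false
M_cit_c	citrate [cytosol]	c	false
M_cit_m	citrate [mitochondrion]	m	false
M_co2_c	carbon dioxide [cytosol]	c	false
M_co2_e	carbon dioxide [extracellular]	e	true
M_co2_m	carbon dioxide [mitochondrion]	m	false
M_coa_m	coenzyme A [mitochondrion]	m	false
M_creat_c	creatine [cytosol]	c	false
M_creat_m	creatine [mitochondrion]	m	false
M_dhap_c	dihydroxyacetone phosphate [cytosol]	c	false
M_e4p_c	erythrose 4-phosphate [cytosol]	c	false
M_f6p_c	fructose 6-phosphate [cytosol]	c	false
M_fad_m	FAD [mitochondrion]	m	false
M_fadh2_m	FADH2 [mitochondrion]	m	false
M_fdp_c	fructose 1,6-bisphosphate [cytosol]	c	false
M_ficytC_m	ferricytochrome c [mitochondrion]	m	false
M_focytC_m	ferrocytochrome c [mitochondrion]	m	false
M_fum_m	fumarate [mitochondrion]	m	false
M_g3p_c	glyceraldehyde 3-phosphate [cytosol]	c	false
M_g6p_c	glucose 6-phosphate [cytosol]	c	false
M_gdp_m	GDP [mitochondrion]	m	false
M_glc_DASH_D_c	D-glucose [cytosol]	c	false
M_glc_DASH_D_e	D-glucose [extracellular]	e	true
M_gln_DASH_L_c	L-glutamine [cytosol]	c	false
M_gln_DASH_L_m	L-glutamine [mitochondrion]	m	false
M_glu_DASH_L_c	L-glutamate [cytosol]	c	false
M_glu_DASH_L_m	L-glutamate [mitochondrion]	m	false
M_glyc3p_c	glycerol 3-phosphate [cytosol]	c	false
M_gthox_c	oxidized glutathione [cytosol]	c	false
M_gthrd_c	reduced glutathione [cytosol]	c	false
M_gtp_m	GTP [mitochondrion]	m	false
M_h2o_c	water [cytosol]	c	false
M_h2o_e	water [extracellular]	e	true
M_h2o_m	water [mitochondrion]	m	false
M_h_c	proton [cytosol]	c	false
M_h_e	proton [extracellular]	e	true
M_h_m	proton [mitochondrion]	m	false
M_hco3_m	bicarbonate [mitochondrion]	m	false
M_icit_c	isocitrate [cytosol]	c	false
M_icit_m	isocitrate [mitochondrion]	m	false
M_lac_DASH_L_c	L-lactate [cytosol]	c	false
M_lac_DASH_L_e	L-lactate [extracellular]	e	true
M_mal_DASH_L_c	L-malate [cytosol]	c	false
M_mal_DASH_L_m	L-malate [mitochondrion]	m	false
M_nad_c	NAD+ [cytosol]	c	false
M_nad_m	NAD+ [mitochondrion]	m	false
M_nadh_c	NADH [cytosol]	c	false
M_nadh_m	NADH [mitochondrion]	m	false
M_nadp_c	NADP+ [cytosol]	c	true
M_nadph_c	NADPH [cytosol]	c	true
M_nh4_c	ammonium [cytosol]	c	false
M_nh4_m	ammonium [mitochondrion]	m	false
M_o2_c	oxygen [cytosol]	c	false
M_o2_e	oxygen [extracellular]	e	true
M_o2_m	oxygen [mitochondrion]	m	false
M_oaa_c	oxaloacetate [cytosol]	c	false
M_oaa_m	oxaloacetate [mitochondrion]	m	false
M_pcreat_c	phosphocreatine [cytosol]	c	false
M_pcreat_m	phosphocreatine [mitochondrion]	m	false
M_pep_c	phosphoenolpyruvate [cytosol]	c	false
M_pi_c	inorganic phosphate [cytosol]	c	false
M_pi_m	inorganic phosphate [mitochondrion]	m	false
M_pyr_c	pyruvate [cytosol]	c	false
M_pyr_e	pyruvate [extracellular]	e	true
M_pyr_m	pyruvate [mitochondrion]	m	false
M_q10_m	ubiquinone-10 [mitochondrion]	m	false
M_q10h2_m	ubiquinol-10 [mitochondrion]	m	false
M_r5p_c	ribose 5-phosphate [cytosol]	c	false
M_ru5p_DASH_D_c	ribulose 5-phosphate [cytosol]	c	false
M_s7p_c	sedoheptulose 7-phosphate [cytosol]	c	false
M_succ_m	succinate [mitochondrion]	m	false
M_succoa_m	succinyl-CoA [mitochondrion]	m	false
M_sucsal_m	succinate semialdehyde [mitochondrion]	m	false
M_xu5p_DASH_D_c	xylulose 5-phosphate [cytosol]	c	false
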