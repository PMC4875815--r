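species	light_level	n_patches_measured	n_real_1	n_real_1.5	n_real_2	n_ideal_1	n_ideal_1.5	n_ideal_2
Formicarius_analis	low	10	6	4	0	6	4	1
Sclerurus_mexicanus	low	9	6	2	1	7	4	1
Sclerurus_caudacutus	low	9	1	1	0	1	1	0
Synallaxis_rutilans	low	9	1	0	0	1	0	0
Dendrocincla_merula	intermediate	9	1	0	0	1	0	0
Dendrocincla_fuliginosa	intermediate	9	1	0	0	3	0	0
Deconychura_stictolaema	intermediate	6	2	0	0	4	1	0
Deconychura_longicauda	intermediate	6	1	0	0	1	0	0
Sittasomus_griseicapillus	intermediate	9	2	0	0	2	0	0
Glyphorynchus_spirurus	intermediate	8	0	0	0	0	0	0
Xiphorhynchus_ocellatus	intermediate	6	1	1	0	3	2	0
Xiphorhynchus_elegans	intermediate	6	1	0	0	2	0	0
Dendrexetastes_rufigula	intermediate	9	0	0	0	0	0	0
Dendrocolaptes_certhia	intermediate	5	0	0	0	0	0	0
Dendrocolaptes_picumnus	intermediate	9	1	0	0	1	0	0
Hylexetastes_perrotii	intermediate	9	5	3	2	5	3	2
Xenops_minutus	intermediate	10	3	0	0	3	0	0
Hylocistes_subulatus	intermediate	7	3	0	0	5	2	0
Automolus_ochrolaemus	intermediate	9	3	1	0	2	1	0
Automolus_infuscatus	intermediate	9	0	0	0	0	0	0
Philydor_pyrrhodes	intermediate	9	2	0	0	2	0	0
Philydor_erythrocercum	intermediate	9	3	3	1	3	3	1
Xiphorhynchus_picus	high	7	0	0	0	0	0	0
Xiphorhynchus_guttatus	high	6	0	0	0	0	0	0
Lepidocolaptes_albolineatus	high	8	8	7	5	8	7	5
Xiphocolaptes_promeropirhynchus	high	8	2	1	0	2	1	0
Furnarius_minor	high	10	6	1	1	7	1	1
Furnarius_leucopus	high	10	7	6	3	7	6	3
Ancistrops_strigilatus	high	6	6	6	3	6	6	3
Philydor_erythropterum	high	9	2	1	0	2	1	0
Synallaxis_albescens	high	9	7	4	2	7	4	2
Synallaxis_gujanensis	high	9	4	2	0	4	2	0
Cranioleuca_vulpina	high	9	6	5	2	7	5	2
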