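edge_u	edge_v	curv_control	curv_disease	delta	z	weight_delta	norm_delta
L_Precuneous_Ctx_Superior_Lateral_Occipital_Ctx_128	R_Superior_Lateral_Occipital_Ctx_Superior_Parietal_Lobule_Precuneous_Ctx_143	24.066	140.784	-116.717	3.3	-0.059	-0.927
M_ACC_156	L_Central_Opercular_Ctx_Frontal_Operculum_Ctx_Insular_Ctx_Putamen_198	1.050	114.517	-113.466	2.3	-0.303	-0.898
M_Juxtapositional_Lobule_Ctx_75	L_Central_Opercular_Ctx_Frontal_Operculum_Ctx_Insular_Ctx_Putamen_198	1.338	106.521	-105.182	2.3	-0.142	-0.823
R_Insular_Ctx_Frontal_Oper_Ctx_3	L_Central_Opercular_Ctx_Frontal_Operculum_Ctx_Insular_Ctx_Putamen_198	1.421	88.785	-87.363	2.5	-0.194	-0.663
L_Postcentral_81	R_Postcentral_Superior_Parietal_Lobule_Precuneous_Ctx_158	38.621	109.428	-70.806	1.8	-0.106	-0.514
R_Frontal_Pole_1	L_Frontal_Pole_122	10.066	32.734	-22.667	1.4	-0.017	-0.081
R_Superior_Parietal_Lobule_Lateral_Occipital_Ctx_12	R_Superior_Lateral_Occipital_Ctx_Superior_Parietal_Lobule_Precuneous_Ctx_143	99.605	2.126	97.478	-1.3	-0.081	1.000
R_Superior_Lateral_Occipital_Ctx_Precuneous_Ctx_20	L_Superior_Lateral_Occipital_Ctx_Precuneous_Ctx_98	47.386	1.829	45.556	-1.8	-0.031	0.533
R_Superior_Lateral_Occipital_Ctx_Precuneous_Ctx_20	L_Precuneous_Ctx_Superior_Lateral_Occipital_Ctx_128	0.698	49.314	-48.615	1.5	-0.107	-0.314
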