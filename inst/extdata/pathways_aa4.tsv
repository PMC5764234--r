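amino_acid	variant_id	step_index	reaction_id
his	v1	1	atp_phosphoribosyltransferase
his	v1	2	pr_atp_diphosphatase
his	v1	3	pr_amp_cyclohydrolase
his	v1	4	profar_isomerase
his	v1	5	igp_synthase
his	v1	6	igp_dehydratase
his	v1	7	histidinol_phosphate_transaminase
his	v1	8	histidinol_phosphate_phosphatase
his	v1	9	histidinol_dehydrogenase
met	duf39	1	aspartate_semialdehyde_dehydrogenase
met	duf39	2	duf39_sulfur_transfer
met	duf39	3	nil_ferredoxin_reduction
met	duf39	4	cog2122_activation
met	duf39	5	methionine_synthase
met	succinyl	1	homoserine_dehydrogenase
met	succinyl	2	homoserine_o_succinyltransferase
met	succinyl	3	cystathionine_gamma_synthase
met	succinyl	4	cystathionine_beta_lyase
met	succinyl	5	methionine_synthase
ser	v1	1	phosphoglycerate_dehydrogenase
ser	v1	2	phosphoserine_transaminase
ser	v1	3	phosphoserine_phosphatase
thr	v1	1	aspartate_kinase
thr	v1	2	aspartate_semialdehyde_dehydrogenase
thr	v1	3	homoserine_dehydrogenase
thr	v1	4	homoserine_kinase
thr	v1	5	threonine_synthase
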