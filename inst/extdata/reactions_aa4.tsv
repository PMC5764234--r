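reaction_id	name	is_transaminase
atp_phosphoribosyltransferase	ATP phosphoribosyltransferase (HisG)	FALSE
pr_atp_diphosphatase	Phosphoribosyl-ATP diphosphatase (HisE/MazG-family)	FALSE
pr_amp_cyclohydrolase	Phosphoribosyl-AMP cyclohydrolase (HisI)	FALSE
profar_isomerase	ProFAR isomerase (HisA)	FALSE
igp_synthase	Imidazole-glycerol-phosphate synthase (HisHF)	FALSE
igp_dehydratase	Imidazoleglycerol-phosphate dehydratase (HisB-N)	FALSE
histidinol_phosphate_transaminase	Histidinol-phosphate transaminase (HisC)	TRUE
histidinol_phosphate_phosphatase	Histidinol-phosphate phosphatase	FALSE
histidinol_dehydrogenase	Histidinol dehydrogenase (HisD)	FALSE
aspartate_semialdehyde_dehydrogenase	Aspartate-semialdehyde dehydrogenase (Asd)	FALSE
duf39_sulfur_transfer	DUF39 reductive sulfur transfer to aspartate semialdehyde	FALSE
nil_ferredoxin_reduction	NIL/ferredoxin-domain reduction step of homocysteine formation	FALSE
cog2122_activation	COG2122-dependent activation step of homocysteine formation	FALSE
methionine_synthase	Methionine synthase	FALSE
homoserine_dehydrogenase	Homoserine dehydrogenase	FALSE
homoserine_o_succinyltransferase	Homoserine O-succinyltransferase (MetA)	FALSE
cystathionine_gamma_synthase	Cystathionine gamma-synthase (MetB)	FALSE
cystathionine_beta_lyase	Cystathionine beta-lyase (MetC)	FALSE
phosphoglycerate_dehydrogenase	D-3-phosphoglycerate dehydrogenase (SerA)	FALSE
phosphoserine_transaminase	Phosphoserine transaminase (SerC)	TRUE
phosphoserine_phosphatase	Phosphoserine phosphatase (SerB)	FALSE
aspartate_kinase	Aspartate kinase	FALSE
homoserine_kinase	Homoserine kinase (ThrB)	FALSE
threonine_synthase	Threonine synthase (ThrC)	FALSE
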