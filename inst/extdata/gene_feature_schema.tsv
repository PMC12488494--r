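name	kind
antibody_count	continuous
loeuf	continuous
missense_oe	continuous
pli	continuous
tau_tissue_specificity	continuous
fpocket_count	continuous
fpocket_max_druggability	continuous
predicted_haploinsufficiency	continuous
predicted_triplosensitivity	continuous
depmap_mean_dependency	continuous
gtex_median_tpm	continuous
protein_length	continuous
ppi_degree	continuous
paralog_count	continuous
gofcards_variant_count	continuous
clinvar_pathogenic_count	continuous
ot_target_priority	continuous
expression_breadth	continuous
promoter_cpg_density	continuous
aa_hydrophobicity	continuous
gene_age	continuous
oncogene	binary
tumor_suppressor	binary
hpa_membrane	binary
hpa_secreted	binary
hpa_intracellular	binary
enzyme	binary
gpcr	binary
transcription_factor	binary
transporter	binary
voltage_gated_ion_channel	binary
omim_autosomal_dominant	binary
omim_autosomal_recessive	binary
depmap_common_essential	binary
depmap_strongly_selective	binary
clingen_haploinsufficient	binary
gofcards_gof_mechanism	binary
predicted_gof_mechanism	binary
predicted_lof_mechanism	binary
predicted_dominant_negative	binary
has_mouse_knockout	binary
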