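feature	group	af_bin	semantics
eqtl_inhibitor	common	common	mechanism_inhibitor
eqtl_activator	common	common	mechanism_activator
l2g_inhibitor	common	common	mechanism_inhibitor
l2g_activator	common	common	mechanism_activator
rare_finngen_gof	rare	rare	gof
rare_finngen_lof_hc	rare	rare	lof
rare_finngen_lof_lc	rare	rare	lof
rare_finngen_missense_damaging	rare	rare	lof
rare_finngen_missense_benign	rare	rare	none
rare_finngen_other	rare	rare	none
rare_finngen_unknown	rare	rare	none
rare_genebass_gof	rare	rare	gof
rare_genebass_lof_hc	rare	rare	lof
rare_genebass_lof_lc	rare	rare	lof
rare_genebass_missense_damaging	rare	rare	lof
rare_genebass_missense_benign	rare	rare	none
rare_genebass_other	rare	rare	none
rare_genebass_unknown	rare	rare	none
burden_finngen_plof	burden	ultrarare	lof
burden_finngen_missense	burden	ultrarare	lof
burden_finngen_plof_missense	burden	ultrarare	lof
burden_genebass_plof	burden	ultrarare	lof
burden_genebass_missense	burden	ultrarare	lof
burden_genebass_plof_missense	burden	ultrarare	lof
burden_meta_plof	burden	ultrarare	lof
burden_meta_missense	burden	ultrarare	lof
burden_meta_plof_missense	burden	ultrarare	lof
clinvar_gof	complementary	none	gof
clinvar_lof	complementary	none	lof
mouse_ko	complementary	none	lof
expression_dir	complementary	none	lof
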