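key	value
n_snp_retained	395
ld_alpha_PL	0.259641353238631
ld_alpha_DE	0.23108332193424
ld_beta_PL	0.0140566975346183
ld_beta_DE	0.0232587021269389
ld_beta_ratio	1.65463488629944
base_freq_correlation	0.945710635689224
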