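statistic	printed	tolerance	cmp
total_genotyped_males	599	0	abs
overall_dmp_pct	6.8	0.05	abs
overall_dmp_ci_low_pct	5.0	0.05	abs
overall_dmp_ci_high_pct	9.2	0.05	abs
dmp_capisr	0.16	0.005	abs
dmp_se_capisr	0.05	0.005	abs
dmp_capval	0.02	0.005	abs
kruskal_wallis_private_alleles_H	5.68	0.005	abs
cohens_d_private_mainland_captive	1.52	0.005	abs
cohens_d_private_island_captive	1.41	0.005	abs
cohens_d_private_mainland_island	1.09	0.005	abs
prop_test_nice11_nice13_chi2	0.760	0.0005	abs
prop_test_nice11_nice13_p	0.383	0.0005	abs
habitat_lr_chisq	7.0710	0.005	abs
habitat_lr_p	0.029	0.0005	abs
welch_t_allele_counts	-0.88	0.005	abs
welch_df_allele_counts	15	0.5	abs
welch_t_ho	-0.54	0.005	abs
welch_df_ho	36	0.5	abs
all_homozygous_probability	0.0023	NA	order_of_magnitude
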