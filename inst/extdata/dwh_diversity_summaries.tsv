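study	index	oiled_mean	oiled_sd	oiled_n	oiled_ad_p	control_mean	control_sd	control_n	control_ad_p	published_welch_p	recoverable
mesocosm	functional_1D	191	18.4	12	0.0006	106	31.9	9	0.353	1.14e-05	FALSE
mesocosm	taxonomic_2D_16S	274	146	4	NA	896	85.8	3	NA	8.89e-04	TRUE
mesocosm	taxonomic_2D_V4	67.3	35.8	7	NA	201	11.3	5	NA	1.50e-05	TRUE
field	functional_1D	199	16.5	6	NA	116	33.4	8	0.770	7.28e-05	TRUE
field	taxonomic_2D_16S	304	124	6	NA	775	304	3	NA	1.23e-01	TRUE
field	taxonomic_2D_V4	84.7	34.2	12	0.502	332	67.3	19	0.529	8.54e-14	TRUE
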