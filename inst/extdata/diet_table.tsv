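diet_set	diet	printed_ratio	protein_ug_mg	lipid_ug_mg	n
altered_multifloral_2020	control_unaltered	5.5	191.40	34.40	44
altered_multifloral_2020	modified_control	5.5	327.72	59.54	42
altered_multifloral_2020	high_lipid	0.4	191.40	443.18	42
altered_multifloral_2020	mid_range	6.6	228.30	34.40	48
altered_multifloral_2020	high_protein	14.5	498.36	34.40	33
monofloral_2022	Juglans_nigra	0.6	51.38	81.63	35
monofloral_2022	Plantago_lanceolata	1.4	125.23	87.64	35
monofloral_2022	Salix_nigra	2.5	115.90	46.22	35
monofloral_2022	Dactylis_glomerata	4.2	111.09	26.33	35
monofloral_2022	Acer_rubrum	6.3	217.76	34.38	35
natural_multifloral_2022	high_lipid	1.0	83.17	82.73	35
natural_multifloral_2022	mid_range_1	2.9	87.95	29.61	35
natural_multifloral_2022	mid_range_2	5.2	77.51	14.90	35
natural_multifloral_2022	high_protein	10.5	104.62	9.88	35
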