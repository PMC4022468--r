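panel	g2	n_baba	n_abba	printed_dstat_pct	printed_digits
neanderthal	NA19720_MXL	61869	62711	-0.676	3
neanderthal	HG01271_CLM	62637	63033	-0.315	3
neanderthal	HG01060_PUR	63134	63171	-0.029	3
neanderthal	NA19908_ASW	72284	69292	2.113	3
neanderthal	NA19401_LWK	73400	70380	2.100	3
neanderthal	NA19236_YRI	73774	69606	2.907	3
neanderthal	NA18978_JPT	61398	62449	-0.849	3
neanderthal	NA18645_CHB	61203	62837	-1.317	3
neanderthal	HG00500_CHS	61443	63314	-1.500	3
neanderthal	SSM097	57291	60031	-2.335	3
neanderthal	NA20755_TSI	61990	63008	-0.814	3
neanderthal	NA07056_CEU	62356	62641	-0.228	3
neanderthal	HG00315_FIN	62523	62366	0.126	3
neanderthal	HG01624_IBS	62210	62496	-0.229	3
neanderthal	HG00261_GBR	62198	61291	0.734	3
denisovan	NA19749_MXL	56423	56824	-0.35	2
denisovan	HG01342_CLM	59852	60988	-0.94	2
denisovan	HG01191_PUR	56526	57331	-0.71	2
denisovan	NA20299_ASW	58889	61285	-1.99	2
denisovan	NA19327_LWK	65428	68000	-1.93	2
denisovan	NA19160_YRI	66408	67672	-0.94	2
denisovan	NA19078_JPT	56313	55554	0.68	2
denisovan	NA18577_CHB	55720	56822	-0.98	2
denisovan	HG00543_CHS	55647	56643	-0.89	2
denisovan	SSM059	52166	52617	-0.43	2
denisovan	NA20813_TSI	56229	56837	-0.54	2
denisovan	NA12775_CEU	56260	55649	0.55	2
denisovan	HG00275_FIN	56541	56308	0.21	2
denisovan	HG01620_IBS	56162	56823	-0.59	2
denisovan	HG00263_GBR	56652	55975	0.60	2
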