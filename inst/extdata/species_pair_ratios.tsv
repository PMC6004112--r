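sample	biomass_ratio	qpcr_dna_extract	qpcr_pcr_products	qpcr_library_prep	count_ratio_5p	count_ratio_3p
MPE5	56.26	1508.46	620.31	122.34	231.35	103.55
MPE4	1	53.92	163.76	19.59	1.83	1.29
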