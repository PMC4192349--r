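gene_id	fc_wt0_mut0	fc_wt6_mut6	fc_wt0_wt6	fc_wt0_wt12	fc_wt0_wt21	gene_function	binding_site_seq
patA (all0521)	-13	-8.0	-1.8	1.6	1.4	Pattern formation	TTGGCTCAAACCCAT
asr1469	-4.0	1.7	NA	Low coverage	NA	Small peptide	TTGGGTCTAACTTAT
asl2028	-2.5	-1.5	-3.7	1.2	1.4	Unknown	TCGGGGTAACAATCC
alr2242	1.3	-13.4	1.5	1.1	2.7	Possible NTPase	None found
alr3758	Low coverage	11 / 0	12	3.9	7.7	Anti sigma factor antagonist	TTGGGTAAACCTGCT
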