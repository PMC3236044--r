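function_id	display_name	patterns	additions	expected_len_aa	len_spread_aa
rps4	30S ribosomal protein S4	30S ribosomal protein S4\b|ribosomal protein S4\b	NA	NA	NA
rpl14	50S ribosomal protein L14	50S ribosomal protein L14\b|ribosomal protein L14\b	NA	NA	NA
eftu	elongation factor Tu	elongation factor Tu\b	NA	NA	NA
alas	alanine--tRNA ligase	alanine--tRNA ligase|alanyl-tRNA synthetase	NA	NA	NA
args	arginine--tRNA ligase	arginine--tRNA ligase|arginyl-tRNA synthetase	NA	NA	NA
trps	tryptophan--tRNA ligase	tryptophan--tRNA ligase|tryptophanyl-tRNA synthetase	NA	NA	NA
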