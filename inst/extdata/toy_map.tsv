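snp_id	chrom	pos
snp1	1	1e+05
snp2	1	2e+05
snp3	1	3e+05
snp4	2	1e+05
snp5	2	2e+05
snp6	2	3e+05
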