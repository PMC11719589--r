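missing_snp	proxy_snp	r2
rs13182402	rs6861395	NA
rs41423247	rs853180	NA
rs2781667	rs2608897	NA
rs37973	rs37972	NA
rs1049793	rs11978239	NA
rs7140310	rs17140310	NA
rs11000016	rs11000000	NA
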