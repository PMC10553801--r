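snp	ref	alt	type	AFR	EUR	EAS	SAS	AMR	cadd	isafe_chb	isafe_ceu
rs2581434	C	G	synonymous	0.246	0.815	0.959	0.860	0.840	12.00	NA	NA
rs1047626	A	G	non-synonymous	0.105	0.757	0.948	0.780	0.768	0.001	1.302	0.588
rs2581452	C	T	intronic	0.193	0.776	0.958	0.800	0.803	11.38	NA	NA
rs2660319	G	A	intronic	0.146	0.756	0.949	0.780	0.770	12.93	1.209	0.588
rs1848182	A	G	intronic	0.193	0.776	0.958	0.800	0.803	10.10	NA	NA
rs2581424	G	A	intronic	0.188	0.776	0.958	0.800	0.804	10.78	NA	NA
rs15857	C	A	synonymous	0.188	0.776	0.958	0.800	0.804	14.93	NA	NA
rs7439806	G	A	intronic	0.188	0.776	0.958	0.800	0.804	10.63	NA	NA
rs55835604	T	A	intronic	0.191	0.776	0.958	0.800	0.804	13.81	NA	NA
rs12510574	G	A	intronic	0.393	0.123	0.037	0.100	0.134	12.13	NA	NA
rs4861014	A	G	intronic	0.067	0.752	0.951	0.780	0.759	12.23	1.343	NA
rs10019356	A	G	intronic	0.176	0.789	0.960	0.820	0.811	15.41	NA	NA
rs7660223	C	T	intronic	0.153	0.789	0.960	0.820	0.808	15.33	NA	NA
rs11051	G	A	3'UTR	0.051	0.751	0.951	0.780	0.758	10.81	1.343	NA
rs11935648	G	A	3'UTR	0.176	0.788	0.960	0.820	0.808	1.44	NA	NA
rs12511999	C	T	3'UTR	0.087	0.751	0.951	0.780	0.764	0.24	1.302	NA
rs10938178	G	C	3'UTR	0.067	0.751	0.951	0.780	0.759	1.32	1.343	NA
rs12512101	C	T	3'UTR	0.086	0.751	0.951	0.780	0.764	4.31	1.302	NA
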