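species	donor_species	donor_evalue	donor_identity	donor_coverage	recipient_species	recipient_evalue	recipient_identity	recipient_coverage	reported_ai
Campylobacter jejuni NCTC12850	Rahnella sp. JUb53	0	98.4	100	Campylobacter jejuni 119462	1e-26	34.1	31	400
Mesorhizobium sp. N.Ca.ET.004.03.1	Enterobacter cloacae	0	99.6	100	Mesorhizobium ciceri	5e-20	31.3	50	413
Rhodobacteraceae bacterium CH30	Neisseriaceae bacterium B2N2-7	0	99.6	100	Rhodobacteraceae bacterium 63075	2e-27	35.4	51	399
Pedobacter himalayensis HHS22	Enterobacter cloacae	0	100	100	Bacteroidetes bacterium	1e-25	31.3	51	403
Streptococcus pneumoniae NCTC7978	Escherichia coli	0	99.8	100	Streptococcus sp. 263_SSPC	1e-36	37.6	54	378
Streptococcus dysgalactiae subsp. equisimilis NCTC11565	Pseudomonas aeruginosa	0	100	100	Streptococcus danieliae	3e-34	36.5	51	383
Listeria monocytogenes str. 104657	Escherichia coli	0	99.6	100	Listeria monocytogenes	3e-29	29.8	51	395
Empedobacter haloabium	Lautropia sp. SCN 69-89	0	91.3	99	Empedobacter brevis	9e-19	32.3	44	419
Helicobacter pametensis NCTC12888	Eikenella corrodens	0	96.7	100	Helicobacter ailurogastricus	7e-35	35.0	57	382
Mumia flava MUSC201	Ralstonia pickettii	0	98.3	100	Cellulomonas sp. HZM	5e-28	35.5	48	398
Mycobacterium abscessus subsp. abscessus str. 226	Bordetella bronchiseptica NCTC8762	0	100	100	Rhodococcus qingshengii S-E5	5e-28	32.9	55	398
Mycobacterium tuberculosis str. 2926STDY5723586	Morganella morganii	0	99.8	100	Rhodococcus qingshengii S-E5	6e-27	32.5	51	400
Streptomyces cavourensis YBQ59	Achromobacter sp. DH1f	0	100	100	Streptomyces sp. WAC00263	4e-28	33.0	48	397
Chryseobacterium sp. 18061	Citrobacter sp. 18056	0	99.4	100	Chryseobacterium sp. F5649	2e-18	29.9	48	420
Aquificaceae bacterium MAG 28	Leucothrix mucor	0	82.4	97	Aquificae bacterium	1e-48	50.1	45	350
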