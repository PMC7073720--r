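genus	species	mmetsp_code	strain	light	day_portion	phosphate_umol_kg	nitrate_umol	salinity_pct	note	geo_area
Akashiwo	sanguinea	MMETSP0223	NA	3800	14	0.3	3	30	NA	New York
Alexandrium	fundyense	MMETSP0196C	NA	200	14	36.2	882	28	NA	Atlantic Ocean
Alexandrium	margalefi	MMETSP0661	NA	60	12	NA	645	35	NA	Tasmania
Alexandrium	minutum	MMETSP0328	NA	100	12	36.2	882	25	NA	Ria da Vigo
Alexandrium	tamarense	MMETSP0380	NA	150	16	3.62	88.2	30	NA	English Channel
Alexandrium	tamarense	MMETSP0378	NA	150	16	3.62	88.2	30	NA	English Channel
Alexandrium	tamarense	MMETSP0384	NA	150	16	3.62	88.2	30	NA	English Channel
Alexandrium	tamarense	MMETSP0382	NA	150	16	3.62	88.2	30	NA	English Channel
Amoebophrya	-	MMETSP0795	NA	200	14	36.2	882	25	NA	-
Amphidinium	carterae	MMETSP0258	NA	60	12	60	60	28	NA	Massachusetts USA
Amphidinium	carterae	MMETSP0259	NA	60	12	60	NA	32	NA	Massachusetts USA
Amphidinium	carterae	MMETSP0398C	NA	200	14	36.2	882	32	NA	Atlantic Ocean
Amphidinium	massartii	MMETSP0689	NA	80	12	25	645	35	NA	Pacific Ocean
Gambierdiscus	australes	MMETSP0766	NA	80	14	25	645	35	NA	Pacific Ocean
Glenodinium	foliaceum	MMETSP0118	NA	550	12	36.2	882	21	Antibiotic	Chesapeake Bay
Glenodinium	foliaceum	MMETSP0119	NA	NA	48hr dark	36.2	882	21	NA	Chesapeake Bay
Karenia	brevis	MMETSP0201	Wilson	50	16	36	883	36	Strain Wilson	Gulf of Mexico
Karenia	brevis	MMETSP0202	Wilson	50	16	36	883	36	NA	Gulf of Mexico
Karenia	brevis	MMETSP0648	Wilson	70	12	36.2	882	35	NA	Gulf of Mexico
Karenia	brevis	MMETSP0649	Wilson	70	12	36.2	882	27	NA	Gulf of Mexico
Karenia	brevis	MMETSP0027	CCMP2229	60	12	60	60	32	Strain CCMP2229	NA
Karenia	brevis	MMETSP0029	CCMP2229	60	12	60	NA	32	NA	NA
Karenia	brevis	MMETSP0030	CCMP2229	60	12	NA	60	32	NA	NA
Karenia	brevis	MMETSP0031	CCMP2229	600	12	60	60	32	NA	NA
Karenia	brevis	MMETSP0573	SP1	70	12	36.2	882	35	Strain SP1	NA
Karenia	brevis	MMETSP0574	SP1	70	12	36.2	882	27	NA	NA
Karenia	brevis	MMETSP0527	SP3	70	12	36.2	882	35	Strain SP3	NA
Karenia	brevis	MMETSP0528	SP3	70	12	36.2	882	27	NA	NA
Kryptoperidinium	foliaceum	MMETSP0120	NA	550	12	36.2	882	21	Antibiotic	California USA
Kryptoperidinium	foliaceum	MMETSP0121	NA	NA	48 h dark	36.2	882	21	Antibiotic	California USA
Lingulodinium	polyedra	MMETSP1034	NA	150	12	36.2	882	28	NA	Gulf of Mexico
Lingulodinium	polyedra	MMETSP1033	NA	150	12	36.2	882	28	NA	Gulf of Mexico
Lingulodinium	polyedra	MMETSP1032	NA	150	12	36.2	882	28	NA	Gulf of Mexico
Lingulodinium	polyedra	MMETSP1035	NA	150	12	36.2	882	28	NA	Gulf of Mexico
Noctiluca	scintillans	MMETSP0253	NA	3800	14	0.3	3	30	NA	Puget Sound, WA
Pelagodinium	beii	MMETSP1338	NA	40	12	36.2	882	35	NA	Caribbean Sea
Polarella	glacialis	MMETSP0227	NA	3800	14	0.3	3	30	NA	McMurdo Sound
Pyrocystis	lunula	MMETSP0229	NA	3800	14	0.3	3	30	NA	-
Scrippsiella	hangoei	MMETSP0359	NA	20	12	50	1000	6.5	Selenium 4.55 nMol/L	Baltic Sea
Scrippsiella	hangoei	MMETSP0360	NA	20	12	36	883	3	NA	Baltic Sea
Scrippsiella	hangoei	MMETSP0361	NA	20	12	36	883	30	NA	Baltic Sea
Togula	jolla	MMETSP0224	NA	3800	14	0.3	3	30	NA	NA
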