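gene_symbol	nucleotide_change	protein_position	ref_aa	alt_aa	class_label	del_count	rsa_percent	on_patch	in_domain	ddg	rvis	flex_percentile	epilepsy_curation
ABCA6	(4075)TGC > CGC	1359	C	R	case	6	2.05	FALSE	TRUE	1.64	0.26	NA	na
ABHD14A	(685)CGA > GGA	227	R	G	case	0	NA	FALSE	TRUE	0.87	0.77	NA	less_likely
ALOX12	(1211)CGG > CAG	404	R	Q	case	4	10.55	TRUE	TRUE	0.90	0.8	NA	likely
DDX52	(1064)ATC > ACC	463	I	T	case	4	4.42	FALSE	TRUE	1.37	0.05	NA	maybe
EPYC	(449)TCC > TGC	150	S	C	case	5	0.77	FALSE	TRUE	-0.41	0.51	NA	no
HELB	(1517)GAT > GGT	506	D	G	case	4	18.27	FALSE	FALSE	1.40	1.08	NA	likely
IAH1	(127)CTG > GTG	43	L	V	case	4	4.66	FALSE	TRUE	2.06	0.17	NA	likely
NMUR1	(409)CGC > TGC	137	R	C	case	4	1.17	FALSE	TRUE	1.83	0.27	NA	no
PALB2	(2993)GGA > GAA	998	G	E	case	5	2.27	FALSE	FALSE	3.23	0.32	97.75	no
EXOG	(830)GGA > GTA	277	G	V	case	6	NA	FALSE	TRUE	1.64	-0.45	NA	na
FAAH2	(821)CGT > CAT	274	R	H	case	4	0	FALSE	TRUE	0.95	-0.29	NA	maybe
MAOA	(374)AAT > AGT	125	N	S	case	4	6.65	FALSE	TRUE	1.36	-0.14	NA	no
PPP1R27	(336)ATA > ATG	112	I	M	case	5	0	FALSE	TRUE	1.41	-0.32	NA	likely
PTPN14	(566)GAA > GGA	189	E	G	case	4	NA	FALSE	TRUE	1.79	-0.30	NA	no
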