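start	stop	size	gene	description	position	NAA01_status	NAA01_gt	NAA02_status	NAA02_gt	NAA03_status	NAA03_gt	NAA04_status	NAA04_gt	NAA05_status	NAA05_gt	NAA06_status	NAA06_gt
347555	348072	517	UBE2L3/AL158801.1	ubiquitin conjugating enzyme E2 L3	intronic	unfiltered	0/1	pass	1/1	absent	0/0	absent	0/0	absent	0/0	pass	1/1
1019583	1027972	8389	TXNRD2	thioredoxin reductase 2	exon (whole)	pass	0/1	pass	0/1	absent	0/0	unfiltered	0/1	absent	0/0	unfiltered	0/1
2166472	2167057	585	No genes	NA	intergenic	pass	1/1	pass	0/1	absent	0/0	pass	1/1	pass	1/1	pass	1/1
2826383	2826602	219	SFSWAP	splicing factor SWAP	intronic	pass	0/1	unfiltered	1/1	pass	1/1	pass	1/1	absent	0/0	pass	1/1
3225855	3226300	445	RIMBP2/RBP2	RIMS binding protein 2	intronic	pass	1/1	absent	0/0	absent	0/0	absent	0/0	absent	0/0	absent	0/0
4106455	4106572	117	LOC107051578	uncharacterized (long non-coding RNA)	intronic	pass	0/1	absent	0/0	absent	0/0	absent	0/0	absent	0/0	unfiltered	0/1
4189586	4189756	170	No genes	NA	intergenic	pass	0/1	absent	0/0	absent	0/0	absent	0/0	absent	0/0	absent	0/0
4264865	4270692	5827	LOC107051609	uncharacterized (long non-coding RNA)	intronic	unfiltered	1/1	unfiltered	0/1	unfiltered	0/1	unfiltered	1/1	absent	0/0	pass	1/1
4280664	4281215	551	LOC107051609	uncharacterized (long non-coding RNA)	intronic	pass	1/1	unfiltered	0/1	pass	1/1	absent	0/0	pass	1/1	absent	0/0
5075785	5076236	451	LOC107051605	uncharacterized (long non-coding RNA)	exon (partial)	pass	1/1	absent	0/0	absent	0/0	absent	0/0	absent	0/0	pass	1/1
5218248	5218471	223	PITPNM2	phosphatidylinositol transfer protein membrane associated 2	intronic	absent	0/0	absent	0/0	absent	0/0	absent	0/0	pass	0/1	pass	0/1
6597976	6598893	917	CORO1C	coronin 1C	intronic	absent	0/0	absent	0/0	absent	0/0	absent	0/0	pass	0/1	pass	1/1
7598349	7598465	116	TTC28	tetratricopeptide repeat domain 28	exon (partial)	absent	0/0	pass	0/1	pass	0/1	absent	0/0	absent	0/0	absent	0/0
7720778	7720969	191	TTC28	tetratricopeptide repeat domain 28	intronic	absent	0/0	absent	0/0	absent	0/0	absent	0/0	pass	0/1	absent	0/0
7746729	7747057	328	SLC2A11L5 (LOC416916)	solute carrier family 2 member 11-like 5	intronic	pass	0/1	absent	0/0	absent	0/0	absent	0/0	pass	0/1	absent	0/0
7838965	7839053	88	ZNRF3	zinc and ring finger 3	intronic	pass	1/1	absent	0/0	absent	0/0	absent	0/0	unfiltered	0/1	absent	0/0
9286836	9287033	197	No genes	NA	intergenic	absent	0/0	pass	1/1	pass	1/1	pass	1/1	unfiltered	1/1	unfiltered	1/1
9608637	9609387	750	No genes	NA	intergenic	absent	0/0	unfiltered	0/1	absent	0/0	absent	0/0	pass	0/1	unfiltered	0/1
10428724	10428823	99	RTN4R	reticulon 4 receptor	intronic	absent	0/0	pass	1/1	absent	0/0	absent	0/0	absent	0/0	absent	0/0
10746849	10747291	442	LOC107054685	uncharacterized (long non-coding RNA)	intronic	pass	1/1	unfiltered	1/1	pass	1/1	absent	0/0	pass	1/1	pass	1/1
12123689	12123786	97	LOC107054674	uncharacterized (long non-coding RNA)	intronic	pass	1/1	absent	0/0	pass	1/1	absent	0/0	absent	0/0	absent	0/0
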