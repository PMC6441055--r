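##fileformat=VCFv4.2
##source=haplochip (REF = FVB/N [A2] base, ALT = 129P2 [A1] base)
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr15	27	snp000001	C	T	.	.	.
chr15	140	snp000002	T	C	.	.	.
chr15	157	snp000003	A	C	.	.	.
chr15	342	snp000004	G	T	.	.	.
chr15	827	snp000005	C	G	.	.	.
chr15	1020	snp000006	C	A	.	.	.
chr15	1108	snp000007	A	T	.	.	.
chr15	1125	snp000008	G	C	.	.	.
chr15	1134	snp000009	C	T	.	.	.
chr15	1326	snp000010	G	A	.	.	.
chr15	1679	snp000011	G	T	.	.	.
chr15	1751	snp000012	T	A	.	.	.
chr15	2069	snp000013	T	C	.	.	.
chr15	2136	snp000014	T	C	.	.	.
chr15	2187	snp000015	T	A	.	.	.
chr15	2415	snp000016	C	G	.	.	.
chr15	2620	snp000017	A	T	.	.	.
chr15	2668	snp000018	A	T	.	.	.
chr15	2837	snp000019	A	C	.	.	.
chr15	2846	snp000020	A	G	.	.	.
chr15	2876	snp000021	T	C	.	.	.
chr15	2878	snp000022	A	G	.	.	.
chr15	3106	snp000023	G	A	.	.	.
chr15	3632	snp000024	A	G	.	.	.
chr15	4228	snp000025	G	A	.	.	.
chr15	4322	snp000026	A	G	.	.	.
chr15	4475	snp000027	G	C	.	.	.
chr15	4603	snp000028	C	A	.	.	.
chr15	5277	snp000029	T	G	.	.	.
chr15	5289	snp000030	A	T	.	.	.
chr15	5294	snp000031	G	A	.	.	.
chr15	5492	snp000032	T	C	.	.	.
chr15	5514	snp000033	C	G	.	.	.
chr15	5533	snp000034	A	C	.	.	.
chr15	5750	snp000035	G	T	.	.	.
chr15	5870	snp000036	A	T	.	.	.
chr15	6084	snp000037	G	A	.	.	.
chr15	6481	snp000038	T	C	.	.	.
chr15	6601	snp000039	G	A	.	.	.
chr15	6729	snp000040	A	C	.	.	.
chr15	6852	snp000041	C	T	.	.	.
chr15	6929	snp000042	T	G	.	.	.
chr15	7107	snp000043	C	G	.	.	.
chr15	7374	snp000044	T	C	.	.	.
chr15	7545	snp000045	C	T	.	.	.
chr15	7661	snp000046	C	T	.	.	.
chr15	7687	snp000047	T	C	.	.	.
chr15	8322	snp000048	A	C	.	.	.
chr15	8482	snp000049	G	A	.	.	.
chr15	8782	snp000050	A	C	.	.	.
chr15	8953	snp000051	A	C	.	.	.
chr15	8972	snp000052	T	C	.	.	.
chr15	9905	snp000053	G	T	.	.	.
chr15	10350	snp000054	T	G	.	.	.
chr15	10658	snp000055	G	T	.	.	.
chr15	10776	snp000056	A	T	.	.	.
chr15	10971	snp000057	C	G	.	.	.
chr15	11066	snp000058	T	A	.	.	.
chr15	11254	snp000059	C	T	.	.	.
chr15	11622	snp000060	G	T	.	.	.
chr15	11739	snp000061	G	T	.	.	.
chr15	11829	snp000062	T	A	.	.	.
chr15	11925	snp000063	C	A	.	.	.
chr15	12013	snp000064	G	A	.	.	.
chr15	12085	snp000065	T	A	.	.	.
chr15	12190	snp000066	C	A	.	.	.
chr15	12398	snp000067	T	A	.	.	.
chr15	12477	snp000068	T	A	.	.	.
chr15	12516	snp000069	T	A	.	.	.
chr15	12657	snp000070	C	T	.	.	.
chr15	12669	snp000071	A	C	.	.	.
chr15	12733	snp000072	G	A	.	.	.
chr15	12868	snp000073	G	C	.	.	.
chr15	12940	snp000074	T	A	.	.	.
chr15	13005	snp000075	T	C	.	.	.
chr15	14235	snp000076	G	T	.	.	.
chr15	14277	snp000077	C	G	.	.	.
chr15	14364	snp000078	C	T	.	.	.
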