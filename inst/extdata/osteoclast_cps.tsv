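# Osteoclast-differentiation cohort design: 16 comparison pairs from 11 public
# expression studies (8 OCU, 8 OCD). Sample columns carry population labels,
# not repository sample accessions; pair each config row with the matching
# series-matrix file to resolve real sample ids.
cp_id	study_id	platform_id	control_label	control_samples	test_label	test_samples	context
1	GSE111237	GPL6885	osteoclast progenitors	osteoclast_progenitors	mature-osteoclast progenitors	mature_osteoclast_progenitors	OCU
2	GSE142866	GPL17021	No RANKL	no_rankl	RANKL	rankl	OCU
3	GSE142866	GPL17021	RANKL	rankl	RANKL with LEA	rankl_with_lea	OCD
4	GSE149887	GPL21103	Mo (macrophages)	mo_macrophages	Oc (osteoclasts)	oc_osteoclasts	OCU
5	GSE17563	GPL339	bone marrow treated with hRANKL 0 hr	hrankl_0hr	bone marrow treated with hRANKL 24h	hrankl_24hr	OCU
6	GSE17563	GPL339	bone marrow treated with hRANKL 0 hr	hrankl_0hr	bone marrow treated with hRANKL 72h	hrankl_72hr	OCU
7	GSE20850	GPL1261	Macrophages	macrophages	Osteoclasts	osteoclasts	OCU
8	GSE30160	GPL1261	WT	wt	RANK IVVY Knockin	rank_ivvy_knockin	OCD
9	GSE37219	GPL8321	WT	wt	NFATc1-deficient OC	nfatc1_deficient_oc	OCD
10	GSE57468	GPL6885	BMM RANKL 1day	bmm_rankl_1day	BMM RANKL 0day	bmm_rankl_0day	OCD
11	GSE57468	GPL6885	BMM RANKL 2day	bmm_rankl_2day	BMM RANKL 0day	bmm_rankl_0day	OCD
12	GSE57468	GPL6885	BMM RANKL 3day	bmm_rankl_3day	BMM RANKL 0day	bmm_rankl_0day	OCD
13	GSE76988	GPL13112	wild-type osteoclast M-CSF RANKL 24H	oc_mcsf_rankl_24h	wild-type osteoclast M-CSF RANKL IL-3 24H	oc_mcsf_rankl_il3_24h	OCD
14	GSE76988	GPL13112	wild-type osteoclast precursor M-CSF 24H	oc_precursor_mcsf_24h	wild-type osteoclast M-CSF RANKL 24H	oc_mcsf_rankl_24h	OCU
15	GSE72846	GPL17021	Control	control	MMP9 KO	mmp9_ko	OCD
16	GSE135479	GPL21103	RANKL	rankl	FOXO3 RANKL	foxo3_rankl	OCU
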