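gene	accession	category	fc_IE	p_IE	fc_LE	p_LE	early_flag
Acta1	NM_009606	actin	-2.2	0.0547	-2.6	0.0487	0
Acta2	NM_007392	actin	-2.8	0.0698	-19.3	0.0139	0
Actg1	NM_009609	actin	-2.1	0.0331	-2.1	0.0331	1
Actg2	NM_009610	actin	-8.6	0.0742	-12.6	0.0552	0
Actn1	NM_134156	focal_adhesion	-3.8	0.0454	-5.3	0.0347	0
Fblim1	NM_133754	focal_adhesion	-1.6	0.1103	-2.5	0.0282	0
Itga7	NM_008398	focal_adhesion	-5.3	0.0179	-7.1	0.0116	0
Itgav	NM_008402	focal_adhesion	-3.7	0.0079	-1.5	0.2389	0
Itgb1	NM_010578	focal_adhesion	-2.1	0.0441	1.1	0.7088	0
Itgb2	NM_008404	focal_adhesion	7.2	0.0059	4.1	0.0365	0
Itgb5	NM_010580	focal_adhesion	1.7	0.0347	2.7	0.0313	0
Lasp1	NM_010688	focal_adhesion	-1.2	0.2772	-2.7	0.0015	0
Nck2	NM_010879	focal_adhesion	1.6	0.0027	2.7	0.0097	0
Parva	NM_020606	focal_adhesion	-2.0	0.0646	-3.3	0.0314	0
Pxn	NM_133915	focal_adhesion	1.4	0.0765	2.2	0.0094	0
Tgfb1i1	NM_009365	focal_adhesion	-3.7	0.0668	-49.0	0.0251	0
Tns1	NM_027884	focal_adhesion	-2.3	0.0520	-5.1	0.0162	0
Vcl	NM_009502	focal_adhesion	-2.4	0.0658	-3.8	0.0355	0
Zyx	NM_011777	focal_adhesion	-3.8	0.0383	-4.5	0.0317	0
Tuba4a	NM_009447	microtubule	1.5	0.0301	-2.2	0.0146	0
Tubb2a	NM_009450	microtubule	-1.2	0.4725	-3.5	0.0007	0
Tubb2b	NM_023716	microtubule	-2.8	0.0200	-3.3	0.0144	0
Tubb2c	NM_146116	microtubule	1.2	0.2601	-2.1	0.0261	0
Tubb3	NM_023279	microtubule	1.5	0.1902	-3.0	0.0362	0
Tubb6	NM_026473	microtubule	-1.2	0.0437	-4.7	0.0013	0
Aspm	NM_009791	mt_binding	-1.7	0.0467	-3.0	0.0300	0
Cenpe	NM_173762	mt_binding	-2.2	0.0246	-3.7	0.0171	0
Ckap2	NM_001004140	mt_binding	1.1	0.3932	-2.2	0.0324	0
Ckap2l	NM_181589	mt_binding	1.0	0.2245	-2.8	0.0050	0
Ckap4	NM_175451	mt_binding	-1.7	0.0290	-3.0	0.0077	0
Dnm2	NM_001039520	mt_binding	1.7	0.2847	4.4	0.0049	0
Dync1i1	NM_010063	mt_binding	1.4	0.4035	6.1	0.0450	0
Incenp	NM_016692	mt_binding	1.1	0.1875	-2.1	0.0379	0
Jub	NM_010590	mt_binding	-3.6	0.0390	-3.2	0.0451	0
Kif1b	NM_008441	mt_binding	-1.9	0.0304	-2.3	0.0195	0
Kif18a	NM_139303	mt_binding	-1.2	0.2028	-2.8	0.0062	0
Kif20a	NM_009004	mt_binding	1.2	0.1513	-2.7	0.0331	0
Kif21a	NM_016705	mt_binding	1.5	0.2060	2.4	0.0334	0
Kif22	NM_145588	mt_binding	1.0	0.2291	-2.7	0.0178	0
Kif23	NM_024245	mt_binding	-1.2	0.0970	-3.4	0.0082	0
Kif26b	NM_001161665	mt_binding	1.0	0.9068	-3.9	0.0102	0
Kif2c	NM_134471	mt_binding	-1.2	0.0918	-2.9	0.0211	0
Kif4	NM_008446	mt_binding	-1.4	0.0966	-2.1	0.0306	0
Klc1	NM_008450	mt_binding	-1.4	0.0455	-2.6	0.0009	0
Klc4	NM_029091	mt_binding	1.3	0.3611	3.1	0.0015	0
Lats2	NM_015771	mt_binding	-3.4	0.0035	-2.7	0.0058	0
Mtap6	NM_010837	mt_binding	-3.0	0.0012	-15.7	0.0004	0
Ndn	NM_010882	mt_binding	-3.7	0.0124	-26.8	0.0017	0
Ninl	NM_207204	mt_binding	-2.6	0.0068	-2.2	0.0029	1
Pea15a	NM_011063	mt_binding	-1.3	0.2698	-2.9	0.0179	0
Prc1	NM_145150	mt_binding	-1.4	0.0245	-2.6	0.0158	0
Shroom3	NM_015756	mt_binding	-1.2	0.3917	2.8	0.0115	0
Tbcel	NM_173038	mt_binding	1.2	0.1501	3.5	0.0292	0
Vav2	NM_009500	mt_binding	-2.1	0.0226	-4.0	0.0062	0
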