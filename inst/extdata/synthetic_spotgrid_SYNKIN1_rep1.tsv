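# kinase=SYNKIN1
# library=ST
# replicate=rep1
position	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y	pT	pY
-5	0.737178	0.835847	0.915851	0.724784	0.708987	0.766116	0.755204	0.834944	0.698074	0.647983	0.761658	0.826436	0.700096	0.860225	3.33691	0.889687	0.603808	0.683003	0.681832	0.613153	0.699427	0.789523
-4	1.01799	1.13335	0.889294	1.08397	0.747228	0.704841	0.945995	0.979922	0.75377	1.03191	0.753837	0.646063	0.78775	1.44993	1.07657	0.885838	1.09476	0.92999	0.928703	0.859905	0.939449	0.802762
-3	0.871399	1.30299	1.06293	0.930836	0.958092	0.786109	0.833257	0.753892	0.51491	0.974786	1.02757	0.969015	0.840794	0.921446	0.758564	0.798749	0.968227	1.24873	1.16347	0.917181	1.14438	0.691326
-2	0.898262	0.979335	1.19366	0.963091	0.916638	0.981451	1.03679	1.01195	1.07159	1.02601	0.976147	0.709343	0.916596	0.824366	0.943811	0.82168	0.986762	0.877979	1.05763	1.00295	0.968123	0.835027
-1	0.939769	0.891515	0.7126	0.707698	0.694934	0.717368	0.933224	0.828369	0.662369	0.937113	0.696739	4.72741	0.669257	0.719681	0.866687	0.740838	0.908601	0.772977	0.904562	0.78646	0.674513	0.757621
+1	0.789039	0.874862	0.667019	4.24662	0.767437	0.746635	0.644748	0.753894	0.743218	0.700493	0.972293	0.987306	0.782918	0.923581	0.758013	0.991255	0.754778	0.769778	0.638422	0.621581	0.636246	0.880617
+2	1.01307	1.01012	1.12792	1.21091	0.917419	1.12631	0.964656	1.26098	1.06033	0.888662	0.811274	0.923247	0.947142	0.687779	0.762308	0.897046	0.906665	0.777903	1.14558	0.790038	1.15693	1.13462
+3	0.914541	0.816803	1.12857	1.12611	0.982223	0.808437	1.0504	0.939743	0.752173	0.844804	0.790685	0.95497	1.1712	0.887363	0.932266	0.916874	1.08168	0.922313	0.880556	0.860303	0.723864	0.919723
+4	0.790053	0.713213	0.979272	0.825031	0.774321	0.962082	0.811583	0.807964	0.901445	0.741391	0.726624	0.873877	0.775121	0.839435	0.691026	4.58687	0.647161	0.762999	0.71696	0.827231	0.702418	0.958701
S	0.580109
T	0.225434
Y	0.0966245
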