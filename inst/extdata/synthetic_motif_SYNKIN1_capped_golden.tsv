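# kinase=SYNKIN1
# library=ST
# stage=capped
# n_replicates=2
position	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y	pT	pY
-5	0.835216	0.951127	0.982783	0.771113	0.789376	0.936657	0.800432	0.877482	0.795736	0.843502	0.847034	0.77273	0.754097	0.931829	4.20852	0.933075	0.864704	0.839269	0.854324	0.774525	0.72146	0.915013
-4	1.02252	1.1301	0.912884	1.06687	0.844905	0.913622	0.999628	1.03524	0.940873	1.15871	0.858803	0.828905	1.03797	1.31993	0.922004	0.870685	1	0.9943	0.925438	1.08091	1.06026	0.983961
-3	1.01832	1.11762	1.14764	1.10687	0.943975	0.899912	0.932411	0.930513	0.779279	0.87035	1.04452	0.963967	0.896419	0.979059	0.919368	1	0.982306	1.21927	1.21712	0.91145	1.18147	0.896704
-2	0.960239	0.867463	1.11895	0.914531	1.03079	0.98052	1.01626	1.00694	0.984134	1.01043	1.16707	0.894115	0.888427	1.01154	1.06596	0.946141	0.961648	1.09114	1.05452	0.963835	1.00819	1.05715
-1	0.86123	0.808077	0.779583	0.732666	0.91935	0.77395	0.934727	0.919158	0.817932	0.925262	0.79537	4.89977	0.774747	0.720992	0.843967	0.821159	0.782143	0.787603	0.778065	0.757229	0.758318	0.808703
+1	0.778843	0.853157	0.767418	4.58728	0.688164	0.924031	0.872122	0.857131	0.852357	0.692217	0.88542	0.860242	0.885679	0.880351	0.7047	0.888329	0.84764	0.849581	0.731536	0.751928	0.79634	1.04553
+2	0.95314	0.915653	1.19102	1.16201	0.885458	1.03599	0.977169	1.20583	1.03534	1.03939	0.881876	1.08778	0.941952	0.845717	0.917647	0.842485	1	0.872135	1.14862	0.859324	1.05657	1.10687
+3	1.00696	1.09184	1.13557	1.10717	1.0609	0.985009	1.13134	0.951402	0.996721	0.98766	0.820398	1.01332	1.05563	0.913584	1.03214	0.848864	1	0.869414	0.899003	1.0143	1.00164	0.988339
+4	0.836716	0.793557	0.914544	0.800945	0.839634	0.950312	0.794828	0.791516	0.923104	0.792779	0.684132	0.827442	0.822612	0.923991	0.877217	1	0.709271	0.931419	0.849212	0.850714	0.7682	0.97372
S	1.9442
T	0.71437
Y	0.341428
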