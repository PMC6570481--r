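# kinase=SYNKIN1
# library=ST
# replicate=rep2
position	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y	pT	pY
-5	1.03363	1.18237	1.14584	0.89005	0.959064	1.24728	0.919732	0.998021	0.990967	1.18422	1.02783	0.746316	0.883053	1.09827	5.75739	1.05857	1.3019	1.12263	1.16228	1.06098	0.80175	1.15868
-4	1.19282	1.30715	1.09135	1.21507	1.11261	1.34255	1.23264	1.27625	1.34488	1.51618	1.13859	1.20917	1.54289	1.35615	0.861105	0.990005	1.26231	1.24089	1.06962	1.55322	1.39382	1.3869
-3	1.46001	1.10658	1.52974	1.61031	1.1384	1.26729	1.28623	1.39471	1.3346	0.918846	1.30623	1.17591	1.17979	1.28406	1.3584	1.62539	1.22578	1.45433	1.57058	1.11048	1.50315	1.39435
-2	1.32658	0.960206	1.33735	1.11076	1.49161	1.26347	1.28177	1.29175	1.14535	1.28125	1.77636	1.41553	1.10603	1.57041	1.54834	1.39706	1.20481	1.70996	1.35583	1.18777	1.35735	1.67883
-1	1.0242	0.9472	1.12243	1.00115	1.52939	1.10029	1.23432	1.3401	1.29829	1.20295	1.18801	6.70288	1.17053	0.952293	1.08041	1.19611	0.852155	1.05894	0.846724	0.956853	1.1182	1.13832
+1	0.928179	1.00221	1.06686	6.0194	0.723225	1.3625	1.36862	1.17931	1.18167	0.826028	0.951382	0.865502	1.21319	1.00543	0.779026	0.932767	1.15352	1.13786	1.0134	1.08942	1.18416	1.49229
+2	1.11788	1.02549	1.57799	1.39457	1.06963	1.18199	1.24313	1.44138	1.26694	1.50267	1.19975	1.58152	1.17569	1.26899	1.35588	0.986019	1.47552	1.21854	1.44595	1.16971	1.19467	1.3531
+3	1.28825	1.63306	1.32142	1.25357	1.33199	1.3766	1.41644	1.11494	1.48198	1.3341	0.987983	1.24956	1.06345	1.09093	1.32742	0.88883	1.26758	0.932989	1.06358	1.37994	1.53256	1.23458
+4	1.07878	1.06955	1.0303	0.944246	1.10632	1.14195	0.946224	0.942588	1.15181	1.03136	0.778345	0.947766	1.06267	1.23378	1.30753	4.9772	0.943474	1.35067	1.20407	1.06602	1.01995	1.2049
S	0.916355
T	0.317603
Y	0.16909
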