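gene	BLIA	BLIS	LAR	MES
CXCL9	1.2135	-0.8256	-0.4544	-0.4632
CXCL10	1.2945	-0.5015	-0.376	-0.5478
CXCL11	1.223	-0.3639	-0.3817	-0.3052
GZMB	1.137	-0.4503	-0.4041	-0.5365
PRF1	1.1887	-0.5636	-0.2632	-0.2878
CD2	1.1965	-0.1813	-0.616	-0.253
CD3D	1.343	-0.4806	-0.3976	-0.5478
CD8A	1.0632	-0.1463	-0.7287	-0.3307
IDO1	1.0455	-0.3193	-0.412	-0.3889
STAT1	1.354	-0.2593	-0.4653	-0.5253
GBP5	1.3807	-0.4605	-0.5212	-0.3466
CCL5	0.9958	-0.3693	-0.4468	-0.4103
IFNG	1.2486	-0.4056	-0.4523	-0.4409
LAG3	1.3233	-0.8019	-0.487	-0.7434
CTLA4	1.2828	-0.3761	-0.4829	-0.4972
TIGIT	1.2758	-0.426	-0.619	-0.6279
IL2RB	1.2882	-0.5754	-0.245	-0.3505
KLRD1	1.2265	-0.4566	-0.7059	-0.381
NKG7	1.2233	-0.3624	-0.4171	-0.4279
SOX8	-0.4925	1.3506	-0.3386	-0.5386
VTCN1	-0.2072	1.2454	-0.591	-0.6056
FOXC1	-0.5192	1.1802	-0.6675	-0.6354
MIA	-0.503	1.3715	-0.5146	-0.5848
ELF5	-0.4039	1.1808	-0.6996	-0.4657
SOX10	-0.3168	1.2748	-0.5925	-0.4471
ROPN1	-0.5939	1.2251	-0.5478	-0.2487
GABRP	-0.4304	1.1996	-0.3064	-0.4279
SERPINB5	-0.3003	1.4617	-0.3909	-0.6188
KRT16	-0.6216	1.2741	-0.6404	-0.4234
SFRP1	-0.3901	1.3439	-0.2676	-0.2959
TTYH1	-0.4919	1.7097	-0.2394	-0.5799
COL9A3	-0.61	1.3899	-0.6539	-0.4752
HORMAD1	-0.5009	1.3963	-0.4044	-0.6152
ART3	-0.2601	0.9351	-0.5045	-0.4959
OPRK1	-0.4767	1.5638	-0.8075	-0.4321
NFIB	-0.3349	1.3625	-0.471	-0.5754
TUBB2B	-0.1682	1.3764	-0.5935	-0.533
CHODL	-0.6094	1.3091	-0.3387	-0.2239
AR	-0.5633	-0.6738	1.3241	-0.361
FOXA1	-0.3591	-0.5238	1.1805	-0.5628
KRT18	-0.5179	-0.4853	1.1733	-0.7292
SPDEF	-0.3398	-0.4543	1.5724	-0.635
PIP	-0.5678	-0.2184	1.2452	-0.3172
AGR2	-0.6567	-0.6539	1.4178	-0.4188
TFF1	-0.4018	-0.913	1.1666	-0.2852
TFF3	-0.16	-0.4282	1.3865	-0.4157
XBP1	-0.5947	-0.3118	1.5983	-0.4222
CA12	-0.514	-0.3209	1.2074	-0.3128
ERBB4	-0.639	-0.4083	1.4326	-0.4304
MLPH	-0.542	-0.6997	1.2094	-0.4948
DHRS2	-0.9054	-0.5746	1.3395	-0.2853
AZGP1	-0.3109	-0.4157	1.2891	-0.0443
SCUBE2	-0.4513	-0.3233	1.1553	-0.8422
GATA3	-0.7998	-0.3383	1.2627	-0.2633
TOX3	-0.5915	-0.3399	1.3919	-0.4982
ANKRD30A	-0.6065	-0.2484	1.2024	-0.4423
PGR	-0.295	-0.3819	1.4185	-0.5958
COL1A1	-0.4533	-0.4487	-0.4367	1.403
COL5A2	-0.5464	-0.2965	-0.5239	1.2323
FBN1	-0.6524	-0.3708	-0.3753	1.1581
SPARC	-0.6684	-0.4637	-0.2006	1.405
THBS2	-0.537	-0.2749	-0.8367	1.2416
POSTN	-0.5447	-0.5338	-0.2003	1.3236
ZEB1	-0.7202	-0.4659	-0.5206	1.3431
TWIST1	-0.3121	-0.6184	-0.3613	1.458
PDGFRB	-0.5318	-0.1851	-0.276	1.1196
FAP	-0.4189	-0.3875	-0.2498	1.396
ACTA2	-0.331	-0.4542	-0.1842	1.1757
TAGLN	-0.4175	-0.5439	-0.2353	1.1891
VCAN	-0.5236	-0.4099	-0.2919	1.3724
LUM	-0.3569	-0.4841	-0.4676	1.3556
DCN	-0.4818	-0.3072	-0.5928	1.2624
MMP2	-0.6178	-0.4221	-0.5216	1.4045
FN1	-0.5462	-0.4569	-0.3486	1.2062
CDH11	-0.5453	-0.4371	-0.3784	1.2622
SNAI2	-0.5127	-0.4282	-0.5673	1.2911
NID2	-0.6206	-0.3242	-0.6699	1.2092
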