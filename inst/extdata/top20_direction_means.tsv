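direction	gene_symbol	mean_logFC	mean_beta_control	mean_beta_case	cpg_ids	refseq_ids
low_to_high	SCARA3	0.206323466	0.325088974	0.550743732	cg27024127	NM_182826;NM_016240
low_to_high	DGKA	0.186103880	0.463929373	0.636142842	cg07679948	NM_201445;NM_201554;NM_001345;NM_201444
low_to_high	CHMP6	0.180451113	0.427431010	0.594948176	cg17714010	NM_024591
low_to_high	GRAP2	0.176343218	0.345254507	0.503365491	cg17988310	NM_004810
low_to_high	ANP32A	0.174294498	0.487796838	0.645383927	cg16068038	NM_006305
low_to_high	C15orf28	0.174294498	0.487796838	0.645383927	cg16068038	NR_026808
low_to_high	RUNX2	0.173846695	0.353517831	0.511252409	cg23261343	NM_001015051;NM_001024630;NM_004348
low_to_high	FAM117A	0.171448251	0.476391397	0.648757545	cg18824549	NM_030802
low_to_high	HADHA	0.170528506	0.382071673	0.551263074	cg01188578	NM_000182
low_to_high	CDKL1	0.170304259	0.347179142	0.506939328	cg19930116	NM_004196
low_to_high	LRP12	0.170284430	0.343858054	0.513716775	cg04104738	NM_001135703;NM_013437
low_to_high	SLC6A3	0.170098885	0.441638466	0.586061634	cg21163347	NM_001044
low_to_high	C12orf68	0.168545035	0.386249035	0.541225053	cg15959252	NM_001013635
low_to_high	FAM113B	0.168034390	0.435914187	0.606991496	cg06547285	NM_138371
low_to_high	CFTR	0.166829935	0.346429017	0.511778447	cg09181792	NM_000492
low_to_high	HLA-C	0.165545061	0.360388834	0.527175698	cg01521131	NM_002117
low_to_high	LRIG1	0.163155815	0.401644742	0.554800577	cg02012974	NM_015541
low_to_high	DENND3	0.162320098	0.402965665	0.543888173	cg10113526	NM_014957
low_to_high	PITPNC1	0.161855428	0.366411863	0.520185872	cg02018291	NM_181671;NM_012417
low_to_high	RTEL1	0.161301355	0.424989511	0.558145266	cg11012153	NM_016434;NM_032957
high_to_low	TUBA3E	-0.253582979	0.585531722	0.356951427	cg03206401	NM_207312
high_to_low	ATP11A	-0.249858039	0.555195536	0.337820462	cg21463262	NM_015205;NM_032189
high_to_low	PIGR	-0.245055045	0.566022491	0.338099343	cg09763644	NM_002644
high_to_low	CLPTM1L	-0.220941109	0.600675563	0.383382931	cg05905124;cg07493874;cg13325231;cg14733637	NM_030782
high_to_low	ZCCHC14	-0.212582756	0.625815745	0.415511888	cg06545761	NM_015144
high_to_low	AP2A2	-0.200483242	0.620273306	0.403857224	cg16999994	NM_012305
high_to_low	PARD3	-0.200458597	0.671931754	0.467683729	cg00287536	NM_019619
high_to_low	LOC100310782	-0.196206215	0.690141317	0.495179435	cg08238319	NR_029397
high_to_low	LOC283663	-0.194987713	0.600691974	0.415414743	cg13626582	NR_024433
high_to_low	HSBP1L1	-0.193501967	0.591994938	0.409595168	cg16313807	NM_001136180
high_to_low	PADI2	-0.192135567	0.635289822	0.451695586	cg00569276	NM_007365
high_to_low	DNASE1L3	-0.191755698	0.593708209	0.416646038	cg24163658	NM_004944
high_to_low	FOXK1	-0.190894875	0.637544942	0.456298977	cg04261496	NM_001037165
high_to_low	KCTD5	-0.190602181	0.545845151	0.366788453	cg08055663	NM_018992
high_to_low	RHBDF2	-0.189237826	0.529895316	0.362415650	cg20690125	NM_001005498;NM_024599
high_to_low	LOC100129637	-0.189079286	0.550352070	0.381558926	cg00270654;cg00227665;cg05304979;cg07041681;cg07102001;cg07396047;cg07721872;cg09276655;cg09331545	NR_024488
high_to_low	DMWD	-0.188083011	0.656464140	0.469728042	cg03758011	NM_004943
high_to_low	BCL2L14	-0.187658640	0.590237614	0.412063339	cg20141578	NM_138722;NM_138723;NM_030766
high_to_low	RGS1	-0.186322336	0.663882933	0.486950604	cg10861751	NM_002922
high_to_low	TRAF5	-0.184529767	0.552903195	0.385134487	cg13066703	NM_004619;NM_145759;NM_001033910
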