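endpoint	rank	gene	uni_hr	uni_p
dfs	1	PFKFB4	1.192	<0.001
dfs	2	ALDOA	1.203	0.004
dfs	3	EGLN3	1.094	0.005
dfs	4	CYP4A22	0.939	0.016
dfs	5	PCK1	0.942	0.019
dfs	6	ACADL	0.948	0.026
dfs	7	CYP4A11	0.937	0.033
dfs	8	EHHADH	0.905	0.033
dfs	9	GAPDH	1.185	0.043
dfs	10	HMGCS2	0.922	0.046
dfs	11	ENO2	1.085	0.055
os	1	PFKFB4	1.315	<0.001
os	2	EGLN3	1.188	<0.001
os	3	ALDOA	1.329	<0.001
os	4	GAPDH	1.445	<0.001
os	5	HK2	1.147	<0.001
os	6	ENO2	1.157	0.001
os	7	PFKFB3	1.168	0.001
os	8	HIF1A	1.228	0.004
os	9	HMGCS2	0.907	0.008
os	10	EHHADH	0.908	0.065
os	11	ECI1	0.804	0.082
os	12	LDHB	1.117	0.090
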