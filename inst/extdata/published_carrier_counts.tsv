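# Published gene-level carrier counts of potentially damaging mutations by
# tier, for lethal and unselected prostate cancer cases and Finnish and
# Swedish population controls, with the published two-sided Fisher p-value
# strings (lethal cases versus each comparison cohort). Control carrier
# counts are allele-count estimates under the at-most-one-mutation-per-gene
# assumption.
# n_lethal=122
# n_unselected=60
# n_finnish=3307
# n_swedish=6192
gene	tier	lethal	unselected	finnish	swedish	p_unselected	p_finnish	p_swedish
ERCC3	TIER1	1	0	0	3	1.000	0.036	0.075
RAD18	TIER1	1	0	0	0	1.000	0.036	0.019
ATM	TIER1	4	0	4	10	0.304	<0.001	<0.001
FANCM	TIER1	2	0	89	44	1.000	0.772	0.223
NTHL1	TIER1	2	0	24	39	1.000	0.236	0.187
CHEK2	TIER1	5	0	60	5	0.173	0.080	<0.001
ALL	TIER1	15	0	177	101	0.003	0.004	<0.001
MUTYH	TIER2	0	1	34	75	0.330	0.633	0.406
ERCC3	TIER2	1	1	5	4	0.552	0.195	0.093
HLTF	TIER2	1	0	20	9	1.000	0.534	0.177
POLL	TIER2	1	0	15	28	1.000	0.441	0.433
MRE11A	TIER2	1	0	0	0	1.000	0.036	0.019
ATM	TIER2	2	0	13	28	1.000	0.098	0.114
RECQL	TIER2	1	0	0	13	1.000	0.036	0.239
FAN1	TIER2	1	0	2	16	1.000	0.103	0.283
NEIL1	TIER2	1	0	3	16	1.000	0.135	0.283
POLG	TIER2	5	0	197	190	0.173	0.555	0.429
TP53	TIER2	2	0	3	7	1.000	0.012	0.012
BRCA1	TIER2	1	0	2	5	1.000	0.103	0.111
RECQL5	TIER2	1	0	3	1	1.000	0.135	0.038
CHEK2	TIER2	1	1	2	28	0.552	0.103	0.433
ALL	TIER2	16	3	299	420	0.123	0.148	0.011
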