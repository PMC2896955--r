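genome	wgd	t	n	m	d
S_cerevisiae	yeast	150	5616	4498	135
C_glabrata	yeast	150	5180	4382	252
V_polyspora	yeast	150	5112	4164	202
S_bayanus	yeast	150	5857	4773	186
N_castelli	yeast	150	5213	4053	221
Paramecium	paramecium	20	38626	14576	214
Populus	populus	70	20082	7228	2600
Arabidopsis	arabidopsis	50	25655	13267	2701
fugu	teleost	350	14251	12653	374
medaka	teleost	350	14564	13352	362
stickleback	teleost	350	16726	14876	519
tetraodon	teleost	350	17120	16088	310
chicken	vertebrate	450	10077	8495	686
opossum	vertebrate	450	13339	11589	751
human	vertebrate	450	13828	12144	673
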