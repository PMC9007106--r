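chr4	137274633	137274877	Wnt4_peak_1	0	.	0	-1	-1
chr4	137276223	137277069	Wnt4_peak_2	0	.	0	-1	-1
chr11	59304348	59305664	Wnt9a_peak_1	0	.	0	-1	-1
chr1	74789945	74790493	Wnt10a_peak_1	0	.	0	-1	-1
chr14	65261700	65263591	Fzd3_peak_1	0	.	0	-1	-1
chr5	135252830	135253153	Fzd9_peak_1	0	.	0	-1	-1
chr2	80446164	80447428	Frzb_peak_1	0	.	0	-1	-1
chr10	39164762	39165022	Wisp3_peak_1	0	.	0	-1	-1
chr10	39166088	39167811	Wisp3_peak_2	0	.	0	-1	-1
chr8	95491363	95492299	Csnk2a2_peak_1	0	.	0	-1	-1
chr8	33597563	33598858	Pp2cb_peak_1	0	.	0	-1	-1
chr3	83766029	83766774	Sfrp2_peak_1	0	.	0	-1	-1
chr15	79444678	79446189	Csnk1e_peak_1	0	.	0	-1	-1
chr13	73848779	73850045	Nkd2_peak_1	0	.	0	-1	-1
chr8	88520968	88524273	Nkd1_peak_1	0	.	0	-1	-1
chr14	59625307	59626307	Shisa2_peak_1	0	.	0	-1	-1
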