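gene_id	symbol	chrom	start	end	strand
ENSMUSG00000036856	Wnt4	chr4	137277489	137299726	+
ENSMUSG00000000126	Wnt9a	chr11	59306928	59333552	+
ENSMUSG00000026167	Wnt10a	chr1	74791516	74804179	+
ENSMUSG00000007989	Fzd3	chr14	65201026	65262463	-
ENSMUSG00000049551	Fzd9	chr5	135248938	135251230	-
ENSMUSG00000027004	Frzb	chr2	80411970	80447625	-
ENSMUSG00000062074	Wisp3	chr10	39150971	39163794	-
ENSMUSG00000046707	Csnk2a2	chr8	95446096	95488820	-
ENSMUSG00000009630	Pp2cb	chr8	33599621	33619794	+
ENSMUSG00000027996	Sfrp2	chr3	83766321	83774316	+
ENSMUSG00000022433	Csnk1e	chr15	79417856	79443919	-
ENSMUSG00000021567	Nkd2	chr13	73818534	73847631	-
ENSMUSG00000031661	Nkd1	chr8	88521344	88594887	+
ENSMUSG00000044461	Shisa2	chr14	59625281	59631658	+
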