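WNT_SIGNALING	canonical and non-canonical Wnt pathway members	Wnt4	Wnt9a	Wnt10a	Fzd3	Fzd9	Frzb	Sfrp2	Nkd1	Nkd2
WNT_INHIBITORS	secreted and intracellular Wnt antagonists	Frzb	Sfrp2	Nkd1	Nkd2	Shisa2
CASEIN_KINASES	casein kinase family	Csnk1e	Csnk2a2
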