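case_id	variant	g_ref	g_alt	t_ref	t_alt
FBC01	395-2A>G	52	48	55	45
FBC02	583G>T	49	51	47	53
FBC03	796C>T	50	50	51	49
FBC04	1373T>A	53	47	44	56
FBC05	1685C>T	48	52	50	50
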