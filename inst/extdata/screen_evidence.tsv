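hgvs_c	protein_change	effect	sift	polyphen	helicase_class	splice_transcript	loh	case_carriers	case_n	control_carriers	control_n
383T>G	L128X	nonsense	-	-	not_done	not_done	not_done	1	448	0	1588
516G>A	W172X	nonsense	-	-	not_done	not_done	not_done	1	448	0	1588
796C>T	Q266X	nonsense	-	-	not_done	not_done	retained	1	448	0	1588
395-2A>G	G132fs	splice_canonical	-	-	not_done	aberrant_truncating	retained	1	448	0	1588
644G>A	R215Q	missense	No	Pb	complete_loss	not_done	not_done	1	448	0	1588
1363C>T	R455C	missense	Yes	Pb	complete_loss	not_done	not_done	1	448	1	1588
1373T>A	M458K	missense	Yes	Ps	complete_loss	not_done	retained	1	448	0	1588
1685C>T	T562I	missense	Yes	Pb	complete_loss	not_done	retained	1	448	0	1588
583G>T	A195S	missense	No	No	partial_loss	not_done	retained	1	448	0	1588
1616G>C	R539P	missense	Yes	Ps	normal	not_done	not_done	1	448	0	1588
187T>C	S63P	missense	No	No	normal	not_done	not_done	1	448	0	1588
1382A>G	H461R	missense	Yes	Pb	normal	not_done	not_done	1	448	1	1588
2T>C	M1T	start_loss	Yes	No	not_done	not_done	not_done	4	448	9	748
1088A>G	N363S	missense	No	No	not_done	not_done	not_done	3	448	7	1588
868-12_868-11del	-	intronic	-	-	not_done	normal	not_done	1	448	0	1588
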