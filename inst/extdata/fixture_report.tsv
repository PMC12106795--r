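Run	Precursor.Id	Modified.Sequence	Stripped.Sequence	Precursor.Charge	Q.Value	Channel	Channel.Q.Value	PTM.Q.Value	PTM.Site.Confidence	Channel.L	Channel.H	Ms1.Area	Protein.Group	Genes
A1	AAAS(UniMod:21)AAK_2	AAAS(UniMod:21)AAK	AAASAAK	2	0.01	H	0.01	0.01	0.9	2000	5000		PROT_PEP1	G_PEP1
A1	AAAS(UniMod:21)AAK_2	AAAS(UniMod:21)AAK	AAASAAK	2	0.01	L	0.01	0.01	0.9	2000	5000	2000	PROT_PEP1	G_PEP1
A2	AAAS(UniMod:21)AAK_2	AAAS(UniMod:21)AAK	AAASAAK	2	0.01	H	0.01	0.01	0.9	1500	5000		PROT_PEP1	G_PEP1
A2	AAAS(UniMod:21)AAK_2	AAAS(UniMod:21)AAK	AAASAAK	2	0.2	L	0.2	0.01	0.9	1500	5000	1500	PROT_PEP1	G_PEP1
A3	AAAS(UniMod:21)AAK_2	AAAS(UniMod:21)AAK	AAASAAK	2	0.01	H	0.01	0.01	0.9	1200	5000		PROT_PEP1	G_PEP1
A3	AAAS(UniMod:21)AAK_2	AAAS(UniMod:21)AAK	AAASAAK	2	0.4	L	0.4	0.01	0.9	1200	5000	1200	PROT_PEP1	G_PEP1
B1	AAAS(UniMod:21)AAK_2	AAAS(UniMod:21)AAK	AAASAAK	2	0.01	H	0.01	0.01	0.9	950	5000		PROT_PEP1	G_PEP1
B1	AAAS(UniMod:21)AAK_2	AAAS(UniMod:21)AAK	AAASAAK	2	0.3	L	0.3	0.01	0.9	950	5000	950	PROT_PEP1	G_PEP1
B2	AAAS(UniMod:21)AAK_2	AAAS(UniMod:21)AAK	AAASAAK	2	0.01	H	0.01	0.01	0.9	100	5000		PROT_PEP1	G_PEP1
B2	AAAS(UniMod:21)AAK_2	AAAS(UniMod:21)AAK	AAASAAK	2	0.6	L	0.6	0.01	0.9	100	5000	100	PROT_PEP1	G_PEP1
B3	AAAS(UniMod:21)AAK_2	AAAS(UniMod:21)AAK	AAASAAK	2	0.01	H	0.01	0.01	0.9	50	5000		PROT_PEP1	G_PEP1
B3	AAAS(UniMod:21)AAK_2	AAAS(UniMod:21)AAK	AAASAAK	2	0.9	L	0.9	0.01	0.9	50	5000	50	PROT_PEP1	G_PEP1
A1	GGGT(UniMod:21)GGR_2	GGGT(UniMod:21)GGR	GGGTGGR	2	0.02	H	0.02	0.02	0.8	100	1000		PROT_PEP2	G_PEP2
A1	GGGT(UniMod:21)GGR_2	GGGT(UniMod:21)GGR	GGGTGGR	2	0.04	L	0.04	0.02	0.8	100	1000	100	PROT_PEP2	G_PEP2
A2	GGGT(UniMod:21)GGR_2	GGGT(UniMod:21)GGR	GGGTGGR	2	0.02	H	0.02	0.02	0.8	200	3000		PROT_PEP2	G_PEP2
A2	GGGT(UniMod:21)GGR_2	GGGT(UniMod:21)GGR	GGGTGGR	2	0.04	L	0.04	0.02	0.8	200	3000	200	PROT_PEP2	G_PEP2
A3	GGGT(UniMod:21)GGR_2	GGGT(UniMod:21)GGR	GGGTGGR	2	0.02	H	0.02	0.02	0.8	300	3000		PROT_PEP2	G_PEP2
A3	GGGT(UniMod:21)GGR_2	GGGT(UniMod:21)GGR	GGGTGGR	2	0.9	L	0.9	0.02	0.8	300	3000	300	PROT_PEP2	G_PEP2
B1	GGGT(UniMod:21)GGR_2	GGGT(UniMod:21)GGR	GGGTGGR	2	0.02	H	0.02	0.02	0.8	1000	3000		PROT_PEP2	G_PEP2
B1	GGGT(UniMod:21)GGR_2	GGGT(UniMod:21)GGR	GGGTGGR	2	0.1	L	0.1	0.02	0.8	1000	3000	1000	PROT_PEP2	G_PEP2
B2	GGGT(UniMod:21)GGR_2	GGGT(UniMod:21)GGR	GGGTGGR	2	0.02	H	0.02	0.02	0.8	1200	3000		PROT_PEP2	G_PEP2
B2	GGGT(UniMod:21)GGR_2	GGGT(UniMod:21)GGR	GGGTGGR	2	0.2	L	0.2	0.02	0.8	1200	3000	1200	PROT_PEP2	G_PEP2
B3	GGGT(UniMod:21)GGR_2	GGGT(UniMod:21)GGR	GGGTGGR	2	0.02	H	0.02	0.02	0.8	800	3000		PROT_PEP2	G_PEP2
B3	GGGT(UniMod:21)GGR_2	GGGT(UniMod:21)GGR	GGGTGGR	2	0.7	L	0.7	0.02	0.8	800	3000	800	PROT_PEP2	G_PEP2
A1	VVVY(UniMod:21)VVK_2	VVVY(UniMod:21)VVK	VVVYVVK	2	0.01	H	0.01	0.01	0.5	1500	4000		PROT_PEP3	G_PEP3
A1	VVVY(UniMod:21)VVK_2	VVVY(UniMod:21)VVK	VVVYVVK	2	0.01	L	0.01	0.01	0.5	1500	4000	1500	PROT_PEP3	G_PEP3
A2	VVVY(UniMod:21)VVK_2	VVVY(UniMod:21)VVK	VVVYVVK	2	0.01	H	0.01	0.01	0.5	1500	4000		PROT_PEP3	G_PEP3
A2	VVVY(UniMod:21)VVK_2	VVVY(UniMod:21)VVK	VVVYVVK	2	0.01	L	0.01	0.01	0.5	1500	4000	1500	PROT_PEP3	G_PEP3
A3	VVVY(UniMod:21)VVK_2	VVVY(UniMod:21)VVK	VVVYVVK	2	0.01	H	0.01	0.01	0.5	1500	4000		PROT_PEP3	G_PEP3
A3	VVVY(UniMod:21)VVK_2	VVVY(UniMod:21)VVK	VVVYVVK	2	0.01	L	0.01	0.01	0.5	1500	4000	1500	PROT_PEP3	G_PEP3
B1	VVVY(UniMod:21)VVK_2	VVVY(UniMod:21)VVK	VVVYVVK	2	0.01	H	0.01	0.01	0.5	1500	4000		PROT_PEP3	G_PEP3
B1	VVVY(UniMod:21)VVK_2	VVVY(UniMod:21)VVK	VVVYVVK	2	0.01	L	0.01	0.01	0.5	1500	4000	1500	PROT_PEP3	G_PEP3
B2	VVVY(UniMod:21)VVK_2	VVVY(UniMod:21)VVK	VVVYVVK	2	0.01	H	0.01	0.01	0.5	1500	4000		PROT_PEP3	G_PEP3
B2	VVVY(UniMod:21)VVK_2	VVVY(UniMod:21)VVK	VVVYVVK	2	0.01	L	0.01	0.01	0.5	1500	4000	1500	PROT_PEP3	G_PEP3
B3	VVVY(UniMod:21)VVK_2	VVVY(UniMod:21)VVK	VVVYVVK	2	0.01	H	0.01	0.01	0.5	1500	4000		PROT_PEP3	G_PEP3
B3	VVVY(UniMod:21)VVK_2	VVVY(UniMod:21)VVK	VVVYVVK	2	0.01	L	0.01	0.01	0.5	1500	4000	1500	PROT_PEP3	G_PEP3
A1	LLLS(UniMod:21)LLR_2	LLLS(UniMod:21)LLR	LLLSLLR	2	0.01	H	0.01	0.04	0.6	500	8000		PROT_PEP4	G_PEP4
A1	LLLS(UniMod:21)LLR_2	LLLS(UniMod:21)LLR	LLLSLLR	2	0.01	L	0.01	0.04	0.6	500	8000	500	PROT_PEP4	G_PEP4
A2	LLLS(UniMod:21)LLR_2	LLLS(UniMod:21)LLR	LLLSLLR	2	0.01	H	0.01	0.04	0.6	600	8000		PROT_PEP4	G_PEP4
A2	LLLS(UniMod:21)LLR_2	LLLS(UniMod:21)LLR	LLLSLLR	2	0.02	L	0.02	0.04	0.6	600	8000	600	PROT_PEP4	G_PEP4
A3	LLLS(UniMod:21)LLR_2	LLLS(UniMod:21)LLR	LLLSLLR	2	0.01	H	0.01	0.04	0.6	700	8000		PROT_PEP4	G_PEP4
A3	LLLS(UniMod:21)LLR_2	LLLS(UniMod:21)LLR	LLLSLLR	2	0.03	L	0.03	0.04	0.6	700	8000	700	PROT_PEP4	G_PEP4
B1	LLLS(UniMod:21)LLR_2	LLLS(UniMod:21)LLR	LLLSLLR	2	0.01	H	0.01	0.04	0.6	400	8000		PROT_PEP4	G_PEP4
B1	LLLS(UniMod:21)LLR_2	LLLS(UniMod:21)LLR	LLLSLLR	2	0.2	L	0.2	0.04	0.6	400	8000	400	PROT_PEP4	G_PEP4
B2	LLLS(UniMod:21)LLR_2	LLLS(UniMod:21)LLR	LLLSLLR	2	0.01	H	0.01	0.04	0.6	300	8000		PROT_PEP4	G_PEP4
B2	LLLS(UniMod:21)LLR_2	LLLS(UniMod:21)LLR	LLLSLLR	2	0.3	L	0.3	0.04	0.6	300	8000	300	PROT_PEP4	G_PEP4
B3	LLLS(UniMod:21)LLR_2	LLLS(UniMod:21)LLR	LLLSLLR	2	0.01	H	0.01	0.04	0.6	200	8000		PROT_PEP4	G_PEP4
B3	LLLS(UniMod:21)LLR_2	LLLS(UniMod:21)LLR	LLLSLLR	2	0.4	L	0.4	0.04	0.6	200	8000	200	PROT_PEP4	G_PEP4
A1	EEES(UniMod:21)EEK_2	EEES(UniMod:21)EEK	EEESEEK	2	0.01	H	0.01	0.01	0.7	2000	6000		PROT_PEP5	G_PEP5
A1	EEES(UniMod:21)EEK_2	EEES(UniMod:21)EEK	EEESEEK	2	0.6	L	0.6	0.01	0.7	2000	6000	2000	PROT_PEP5	G_PEP5
A2	EEES(UniMod:21)EEK_2	EEES(UniMod:21)EEK	EEESEEK	2	0.01	H	0.01	0.01	0.7	1800	6000		PROT_PEP5	G_PEP5
A2	EEES(UniMod:21)EEK_2	EEES(UniMod:21)EEK	EEESEEK	2	0.7	L	0.7	0.01	0.7	1800	6000	1800	PROT_PEP5	G_PEP5
A3	EEES(UniMod:21)EEK_2	EEES(UniMod:21)EEK	EEESEEK	2	0.01	H	0.01	0.01	0.7	1500	6000		PROT_PEP5	G_PEP5
A3	EEES(UniMod:21)EEK_2	EEES(UniMod:21)EEK	EEESEEK	2	0.55	L	0.55	0.01	0.7	1500	6000	1500	PROT_PEP5	G_PEP5
B1	EEES(UniMod:21)EEK_2	EEES(UniMod:21)EEK	EEESEEK	2	0.01	H	0.01	0.01	0.7	1000	6000		PROT_PEP5	G_PEP5
B1	EEES(UniMod:21)EEK_2	EEES(UniMod:21)EEK	EEESEEK	2	0.9	L	0.9	0.01	0.7	1000	6000	1000	PROT_PEP5	G_PEP5
B2	EEES(UniMod:21)EEK_2	EEES(UniMod:21)EEK	EEESEEK	2	0.01	H	0.01	0.01	0.7	1100	6000		PROT_PEP5	G_PEP5
B2	EEES(UniMod:21)EEK_2	EEES(UniMod:21)EEK	EEESEEK	2	0.52	L	0.52	0.01	0.7	1100	6000	1100	PROT_PEP5	G_PEP5
B3	EEES(UniMod:21)EEK_2	EEES(UniMod:21)EEK	EEESEEK	2	0.01	H	0.01	0.01	0.7	900	6000		PROT_PEP5	G_PEP5
B3	EEES(UniMod:21)EEK_2	EEES(UniMod:21)EEK	EEESEEK	2	0.8	L	0.8	0.01	0.7	900	6000	900	PROT_PEP5	G_PEP5
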