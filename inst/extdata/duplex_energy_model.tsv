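type	key1	key2	value
init	.	.	4.1
max_loop	.	.	15
stack	AU	AU	-1.3
stack	UA	AU	-1.3
stack	GC	AU	-2.3
stack	CG	AU	-2.3
stack	GU	AU	-1
stack	UG	AU	-1
stack	AU	UA	-1.3
stack	UA	UA	-1.3
stack	GC	UA	-2.3
stack	CG	UA	-2.3
stack	GU	UA	-1
stack	UG	UA	-1
stack	AU	GC	-2.3
stack	UA	GC	-2.3
stack	GC	GC	-3.3
stack	CG	GC	-3.3
stack	GU	GC	-2
stack	UG	GC	-2
stack	AU	CG	-2.3
stack	UA	CG	-2.3
stack	GC	CG	-3.3
stack	CG	CG	-3.3
stack	GU	CG	-2
stack	UG	CG	-2
stack	AU	GU	-1
stack	UA	GU	-1
stack	GC	GU	-2
stack	CG	GU	-2
stack	GU	GU	-0.7
stack	UG	GU	-0.7
stack	AU	UG	-1
stack	UA	UG	-1
stack	GC	UG	-2
stack	CG	UG	-2
stack	GU	UG	-0.7
stack	UG	UG	-0.7
bulge	1	.	3.8
bulge	2	.	4.2
bulge	3	.	4.4
bulge	4	.	4.5
bulge	5	.	4.6
bulge	6	.	4.7
bulge	7	.	4.8
bulge	8	.	4.9
bulge	9	.	4.9
bulge	10	.	5
bulge	11	.	5
bulge	12	.	5.1
bulge	13	.	5.1
bulge	14	.	5.2
bulge	15	.	5.2
interior	2	.	1.5
interior	3	.	1.8
interior	4	.	2
interior	5	.	2.2
interior	6	.	2.3
interior	7	.	2.4
interior	8	.	2.4
interior	9	.	2.5
interior	10	.	2.5
interior	11	.	2.6
interior	12	.	2.6
interior	13	.	2.7
interior	14	.	2.7
interior	15	.	2.8
interior	16	.	2.8
interior	17	.	2.8
interior	18	.	2.8
interior	19	.	2.9
interior	20	.	2.9
interior	21	.	2.9
interior	22	.	2.9
interior	23	.	3
interior	24	.	3
interior	25	.	3
interior	26	.	3
interior	27	.	3
interior	28	.	3.1
interior	29	.	3.1
interior	30	.	3.1
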