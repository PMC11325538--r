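pose	letter	value	uncertainty	scheme
pose 1	m	28.2	0.6	merged
pose 1	alt	29.3	0.4	split
pose 1	e	-0.7	0.3	merged
pose 1	ef	-0.5	0.2	split
pose 1	v	12.2	1.0	merged
pose 1	vw	12.5	0.6	split
pose 1	n	-37.3	0.6	merged
pose 1	bcr	-38.4	0.5	split
pose 2	m	26.5	0.3	merged
pose 2	alt	26.5	0.3	split
pose 2	e	3.2	0.2	merged
pose 2	ef	3.5	0.3	split
pose 2	v	12.4	0.6	merged
pose 2	vw	12.1	0.6	split
pose 2	n	-36.1	0.2	merged
pose 2	bcr	-36.2	0.5	split
pose 3	m	28.2	0.4	merged
pose 3	alt	27.8	0.4	split
pose 3	e	-1.2	0.3	merged
pose 3	ef	-1.4	0.3	split
pose 3	v	12.1	0.4	merged
pose 3	vw	11.5	0.9	split
pose 3	n	-35.4	0.3	merged
pose 3	bcr	-36.5	0.4	split
pose 4	m	31.2	0.6	merged
pose 4	alt	31.6	0.4	split
pose 4	e	0.3	0.3	merged
pose 4	ef	0.5	0.3	split
pose 4	v	7.7	0.9	merged
pose 4	vw	6.6	0.8	split
pose 4	n	-37.6	0.5	merged
pose 4	bcr	-37.4	0.3	split
pose 5	m	26.3	0.3	merged
pose 5	alt	26.5	0.3	split
pose 5	e	3.6	0.1	merged
pose 5	ef	2.8	0.4	split
pose 5	v	12.7	0.4	merged
pose 5	vw	13.5	0.5	split
pose 5	n	-35.3	0.6	merged
pose 5	bcr	-35.9	0.3	split
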