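protocol	system	value	uncertainty
bat1_split_amber	crystal	-6.1	0.6
bat1_split_amber	pose 1	-2.5	0.9
bat1_split_amber	pose 2	-6.7	0.6
bat1_split_amber	pose 3	-2.6	0.8
bat1_split_amber	pose 4	-1.5	0.6
bat1_split_amber	pose 5	-6.5	0.8
split_amber	crystal	-7.0	1.5
split_amber	pose 1	-2.7	1.2
split_amber	pose 2	-5.9	1.5
split_amber	pose 3	-1.7	1.3
split_amber	pose 4	-1.5	1.9
split_amber	pose 5	-7.5	1.2
merged_amber	crystal	-6.8	1.5
merged_amber	pose 1	-3.5	1.0
merged_amber	pose 2	-5.7	0.8
merged_amber	pose 3	-3.3	1.3
merged_amber	pose 4	-2.8	1.5
merged_amber	pose 5	-7.3	1.2
split_openmm	crystal	-6.6	0.8
split_openmm	pose 1	-2.9	0.8
split_openmm	pose 2	-5.9	0.9
split_openmm	pose 3	-1.3	1.1
split_openmm	pose 4	-1.3	1.0
split_openmm	pose 5	-6.8	0.8
merged_openmm	crystal	-6.2	1.1
merged_openmm	pose 1	-2.4	1.4
merged_openmm	pose 2	-6.1	0.7
merged_openmm	pose 3	-3.7	0.8
merged_openmm	pose 4	-1.5	1.2
merged_openmm	pose 5	-7.2	0.8
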