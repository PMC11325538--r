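protocol	pose	replica	value	uncertainty
tevb	pose 1	1	-2.5	1.8
tevb	pose 1	2	-0.5	0.8
tevb	pose 1	3	-3.1	1.4
tevb	pose 1	4	-1.2	1.0
tevb	pose 1	5	-3.4	0.8
tevb	pose 1	6	-1.2	0.9
tevb	pose 2	1	-6.9	1.2
tevb	pose 2	2	-7.2	0.6
tevb	pose 2	3	-4.5	0.6
tevb	pose 2	4	-8.6	1.0
tevb	pose 2	5	-8.1	1.2
tevb	pose 2	6	-6.0	0.9
tevb	pose 3	1	0.0	0.9
tevb	pose 3	2	-1.0	0.9
tevb	pose 3	3	-4.0	1.0
tevb	pose 3	4	-2.2	1.0
tevb	pose 3	5	-2.1	0.6
tevb	pose 3	6	-3.1	1.1
tevb	pose 4	1	-2.0	0.7
tevb	pose 4	2	-0.2	0.7
tevb	pose 4	3	-1.7	1.8
tevb	pose 4	4	-0.6	1.2
tevb	pose 4	5	-2.7	1.5
tevb	pose 4	6	-3.3	1.4
tevb	pose 5	1	-8.6	1.2
tevb	pose 5	2	-8.7	0.9
tevb	pose 5	3	-8.4	1.2
tevb	pose 5	4	-7.4	1.1
tevb	pose 5	5	-6.9	0.9
tevb	pose 5	6	-6.5	0.9
m_star_evbc	pose 1	1	-3.3	1.1
m_star_evbc	pose 1	2	-3.6	1.4
m_star_evbc	pose 1	3	-1.8	1.2
m_star_evbc	pose 1	4	-3.4	1.3
m_star_evbc	pose 1	5	-3.2	1.7
m_star_evbc	pose 1	6	-1.8	1.2
m_star_evbc	pose 2	1	-7.2	1.6
m_star_evbc	pose 2	2	-7.4	1.1
m_star_evbc	pose 2	3	-7.4	0.8
m_star_evbc	pose 2	4	-7.6	1.4
m_star_evbc	pose 2	5	-7.0	1.6
m_star_evbc	pose 2	6	-7.4	1.7
m_star_evbc	pose 3	1	-2.2	0.9
m_star_evbc	pose 3	2	-3.2	1.2
m_star_evbc	pose 3	3	-2.7	1.1
m_star_evbc	pose 3	4	-3.5	1.3
m_star_evbc	pose 3	5	-3.0	0.8
m_star_evbc	pose 3	6	-2.6	1.5
m_star_evbc	pose 4	1	-1.1	1.1
m_star_evbc	pose 4	2	-3.3	1.1
m_star_evbc	pose 4	3	0.5	2.0
m_star_evbc	pose 4	4	-1.3	1.4
m_star_evbc	pose 4	5	-0.7	1.0
m_star_evbc	pose 4	6	-2.4	2.1
m_star_evbc	pose 5	1	-8.1	0.8
m_star_evbc	pose 5	2	-6.2	1.3
m_star_evbc	pose 5	3	-7.2	0.6
m_star_evbc	pose 5	4	-8.9	1.0
m_star_evbc	pose 5	5	-6.9	1.4
m_star_evbc	pose 5	6	-6.8	1.3
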