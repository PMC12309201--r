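genotype	GrainNumber	Biomass	GrainWeight	TillerNumberGain	SpikeNumber	Total
PPPW_017	4	2	1	3	2	1
PPPW_025	6	1	7	1	3	2
PPPW_033	1	5	2	4	4	3
PPPW_023	7	3	5	2	1	4
PPPW_012	5	7	4	6	5	5
PPPW_046	2	4	6	12	10	6
PPPW_016	8	6	3	8	7	7
PPPW_034	3	10	8	7	9	8
PPPW_011	10	8	10	5	6	9
PPPW_007	9	9	9	9	8	10
PPPW_004	11	11	11	10	11	11
PPPW_003	12	12	12	11	12	12
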