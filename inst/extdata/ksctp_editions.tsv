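edition	year	pages	chapters	new_chapters	removed_chapters	citations_total	citations_per_chapter_printed	citations_indexed	persistence_pct
1	1967	1629	53	53	NA	2927	55.2	585	NA
2	1975	2572	52	18	19	9126	175.5	2280	44
3	1980	3306	57	9	4	17030	298.8	4225	56
4	1985	2055	54	3	6	2091	38.7	407	5
5	1989	2158	50	10	14	3999	80.0	780	21
6	1995	2805	53	8	5	8625	162.7	2393	16
7	2000	3345	55	7	5	10180	185.1	4257	23
8	2005	4064	55	2	2	11795	214.5	3780	20
9	2009	4521	59	4	0	10472	177.5	4815	25
10	2017	4533	62	5	2	9235	149.0	4157	26
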