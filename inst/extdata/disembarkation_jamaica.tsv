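decade	Senegambia	Sierra Leone	Gold Coast	Bight of Benin	Bight of Biafra	West-central Africa	Southeast Africa	Total
1651-1660	0	0	0	0	85	0	0	85
1661-1670	0	0	0	704	2101	500	0	3305
1671-1680	158	0	2402	2071	2204	1211	462	8508
1681-1690	960	92	412	9465	2445	7139	171	20684
1691-1700	1447	205	1270	3181	1926	3593	0	11622
1701-1710	1328	413	13445	8918	730	2843	0	27677
1711-1720	813	125	12319	6636	324	1497	385	22099
1721-1730	1603	667	12055	7761	3011	6003	0	31100
1731-1740	303	559	6387	954	4795	7708	0	20706
1741-1750	1993	2142	10062	1155	14868	7134	0	37354
1751-1760	2049	8591	22630	5032	18277	10803	0	67382
1761-1770	634	11523	24387	9264	18347	5133	0	69288
1771-1780	2021	11874	25980	8798	25051	4282	0	78006
1781-1790	1135	5030	36289	7617	34800	3546	0	88417
1791-1800	828	12322	20091	5773	68391	46382	0	153787
1801-1810	246	3260	12763	2882	29248	12970	0	61369
Total	15518	56803	200492	80211	226603	120744	1018	701389
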