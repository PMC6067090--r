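country	year	first_day	min_rate	M	old_rate	population	ratio_a	ratio_b
Denmark	1994	56071	13.0	15	23003	5201016	4320	1772
Denmark	2009	28786	6.6	10	20009	5491215	4406	3062
Finland	1996	36675	13.7	5	24885	5117510	2695	1828
Finland	2011	16811	5.3	10	19169	5466882	3215	3665
Norway	1996	56128	12.0	10	22835	4377175	4712	1917
Norway	2011	25520	3.5	10	19673	5197587	7417	5718
Sweden	1997	44921	11.1	15	22732	8889449	4058	2053
Sweden	2010	27171	6.1	4	21421	9779521	4461	3517
Austria	2002	47444	10.2	10	22083	8168634	4685	2180
Austria	2011	29399	5.0	5	17338	8689683	5953	3511
Czech Republic	1994	110440	24.2	15	40731	10328577	4571	1724
Czech Republic	2015	37853	7.4	4	21979	10636473	5151	2990
Hungary	1996	128436	19.7	5	27794	10255681	6542	1415
Hungary	2010	73429	8.3	10	18176	9885318	8933	2211
Poland	1999	90700	19.6	10	23357	38648841	4646	1196
Poland	2011	39635	9.8	10	17870	38519432	4064	1832
Slovakia	1996	121250	22.5	15	24041	5371977	5400	1070
Slovakia	2009	89761	10.0	4	18151	5439590	9012	1822
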