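gene	LumA	LumB	HER2E	Basal	Normal-like
PAMG01	1.0412	-2.3398	2.4325	0.0487	-0.8641
PAMG02	-2.1594	-0.4124	-0.9877	0.6693	0.9172
PAMG03	0.2785	-1.8612	-0.4556	1.9788	-0.4587
PAMG04	-0.1695	0.8988	-2.2233	1.0008	-3.7139
PAMG05	-1.3333	-1.2896	1.9917	1.1538	-0.5793
PAMG06	-5.0322	-0.4628	1.1237	2.2854	3.5343
PAMG07	-1.4703	-2.4727	-3.1286	-1.4149	-0.8854
PAMG08	-2.0402	-1.9219	2.9622	-1.2371	-1.1777
PAMG09	0.2271	0.2679	-2.3384	-0.0166	-0.2412
PAMG10	-0.9476	-1.9981	-2.104	0.6778	3.3061
PAMG11	-0.8164	-0.2829	-2.9437	2.8108	-1.7427
PAMG12	-1.4609	0.3347	-2.3869	-1.7305	1.5613
PAMG13	-0.4429	-0.3976	-0.696	-1.7479	-1.2278
PAMG14	-0.4516	-0.5824	1.0656	1.5486	-0.6552
PAMG15	-5.0938	-3.4688	-1.422	-0.8038	-0.7104
PAMG16	2.694	-0.5455	-0.398	-0.4303	1.5619
PAMG17	1.2328	-3.5999	-0.5627	1.2105	1.2173
PAMG18	0.4351	2.3055	2.3419	-1.2291	2.1524
PAMG19	-1.6094	-2.0066	4.5775	-1.4488	2.1311
PAMG20	1.3795	0.2964	-2.1377	-0.5139	4.3233
PAMG21	-0.6573	1.039	3.8124	-0.7841	0.1409
PAMG22	-0.3294	0.0109	4.2636	-1.3734	-5.0705
PAMG23	-2.7841	2.694	0.4629	1.7517	-1.0827
PAMG24	2.9316	-1.6941	1.7939	-0.9621	-1.5519
PAMG25	0.0964	0.8868	-3.4776	0.1367	-0.5919
PAMG26	3.8162	-1.9543	0.9377	0.274	2.3027
PAMG27	3.4619	4.249	-1.0883	-3.7175	-1.1378
PAMG28	0.1163	1.3754	-0.3308	0.6926	-1.6116
PAMG29	1.2907	-0.6867	1.1043	3.0033	0.9852
PAMG30	3.4513	1.5703	2.0667	-0.0275	1.4015
PAMG31	-1.0579	-2.3112	-0.0924	-1.5505	-0.4863
PAMG32	0.3328	3.0178	5.2774	2.6223	0.825
PAMG33	-0.5094	-2.311	1.178	0.521	0.9963
PAMG34	0.6656	-3.1136	-0.4048	2.028	0.7354
PAMG35	0.3649	-0.1105	0.8831	0.4312	-1.1412
PAMG36	2.3292	1.6984	-0.2005	1.2268	1.4776
PAMG37	1.187	-0.0222	-2.1868	2.892	-4.5366
PAMG38	-1.7836	-1.5206	1.0065	1.3162	1.2281
PAMG39	1.1545	2.3516	1.8985	0.7505	0.8073
PAMG40	-1.6498	4.8289	0.7656	-1.3494	4.1032
PAMG41	-2.3145	-3.917	0.7432	1.161	0.5265
PAMG42	1.556	2.9472	0.3144	-0.8285	0.2208
PAMG43	-2.4084	-0.9498	1.6959	4.361	2.3915
PAMG44	0.6134	1.9623	-2.5668	0.6857	1.4666
PAMG45	-1.6673	-3.6487	2.3166	-1.596	-0.009
PAMG46	2.8363	-0.5212	-1.8182	3.2821	-0.0424
PAMG47	1.4236	-1.9177	0.67	-0.92	0.277
PAMG48	-0.805	-0.9806	1.5517	-3.1729	-2.1403
PAMG49	1.5987	-2.1546	0.4743	-2.0898	2.4721
PAMG50	0.853	0.7389	-3.1197	0.0833	-1.0796
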