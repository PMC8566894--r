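otu_id	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010	S011	S012
OTU_1	14	1	11	8	10	2	61	135	13	130	0	81
OTU_2	3	5	10	9	22	11	57	125	10	132	0	66
OTU_3	4	11	14	13	9	10	0	0	0	0	0	0
OTU_4	3	14	3	6	7	2	0	0	0	0	0	0
OTU_5	12	8	18	11	12	17	0	1	0	0	0	0
OTU_6	123	124	138	142	130	139	0	0	0	0	0	0
OTU_7	19	21	34	50	26	40	0	0	0	0	0	0
OTU_8	43	31	26	19	25	14	0	0	0	0	0	0
OTU_9	13	3	10	11	8	8	0	0	0	0	0	0
OTU_10	10	17	27	11	19	21	0	0	0	0	0	0
OTU_11	5	6	1	3	1	1	0	0	0	0	0	0
OTU_12	11	13	10	13	38	10	0	0	0	0	0	0
OTU_13	4	4	0	5	3	0	0	0	0	0	0	0
OTU_14	1	0	2	1	4	0	13	36	3	21	0	18
OTU_15	10	14	23	21	16	17	0	3	0	5	0	5
OTU_16	11	2	2	4	12	12	0	0	0	0	0	0
OTU_17	13	22	26	23	7	21	0	0	0	0	0	0
OTU_18	17	10	6	12	16	21	83	232	11	340	5	164
OTU_19	63	68	63	59	99	61	0	1	0	7	0	0
OTU_20	10	4	8	9	2	15	0	0	0	1	0	0
OTU_21	45	24	18	47	35	29	0	0	0	0	0	0
OTU_22	31	34	24	9	31	33	0	0	0	0	0	0
OTU_23	1	13	5	11	19	11	0	0	0	0	0	0
OTU_24	0	17	3	7	4	11	0	4	0	5	0	1
OTU_25	86	123	85	85	96	88	0	0	0	3	0	1
OTU_26	5	8	2	5	2	2	758	396	961	251	995	640
OTU_27	107	85	111	89	105	125	0	0	0	0	0	0
OTU_28	0	0	2	0	1	1	0	0	0	0	0	0
OTU_29	12	8	26	15	4	21	0	0	0	0	0	0
OTU_30	83	86	66	85	48	72	0	0	0	0	0	0
OTU_31	12	16	14	23	6	19	0	0	0	0	0	0
OTU_32	76	76	67	83	69	59	0	0	0	0	0	0
OTU_33	13	9	12	21	19	19	0	0	0	0	0	0
OTU_34	37	49	30	46	28	18	0	0	0	0	0	0
OTU_35	43	37	31	10	35	30	0	0	0	0	0	0
OTU_36	5	4	19	4	4	12	0	0	0	0	0	0
OTU_37	5	5	14	6	10	10	0	0	0	0	0	0
OTU_38	33	12	18	13	12	9	0	2	0	4	0	3
OTU_39	14	4	18	8	2	2	28	65	2	101	0	21
OTU_40	3	12	3	3	4	7	0	0	0	0	0	0
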