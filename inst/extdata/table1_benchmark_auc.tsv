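domain	roc_auc	pr_auc	n_binder	n_nonbinder
DLG4_1	0.53	0.52	7	15
DLG4_3	0.74	0.76	89	5
ErbinLAP2	0.79	0.84	43	13
GIPC1_TIP_2	0.64	0.60	26	13
GOPC	0.32	0.34	13	8
GRIP2_2	0.47	0.69	6	5
GRIP2_3	0.78	0.82	8	5
InaDl_1	0.66	0.74	48	7
InaDl_2	0.80	0.86	53	7
InaDl_3	0.71	0.74	67	7
InaDl_4	0.68	0.75	40	7
InaDl_5	0.67	0.64	43	7
InaDl_6	0.60	0.58	41	6
InaDl_7	0.56	0.54	36	7
InaDl_8	0.45	0.52	30	6
InaDl_9	0.43	0.52	31	7
LIN7B	0.14	0.31	11	6
MAGI1_3	0.86	0.86	53	27
MAGI1_5	0.75	0.70	14	30
MAGI2_1	0.84	0.86	22	10
MAGI2_4	0.68	0.78	21	15
MAGI2_5	0.68	0.73	20	16
MAGI2_6	0.77	0.79	21	9
MAGI3_1	0.68	0.64	11	12
MAGI3_2	0.78	0.82	11	9
MAGI3_3	0.77	0.82	19	11
MAGI3_4	0.90	0.93	30	12
MUPP1_10	0.69	0.68	39	5
MUPP1_11	0.78	0.83	18	8
MUPP1_12	0.81	0.81	25	8
MUPP1_13	0.86	0.86	42	6
MUPP1_1	0.97	0.98	79	5
MUPP1_2	0.93	0.94	53	5
MUPP1_3	0.94	0.95	53	5
MUPP1_4	0.93	0.95	19	5
MUPP1_5	0.94	0.96	37	5
MUPP1_6	0.80	0.88	12	5
MUPP1_7	0.94	0.96	32	5
MUPP1_8	0.85	0.85	18	6
MUPP1_9	0.93	0.95	37	6
PICK1	0.51	0.56	36	6
PTPN13_PTPL1_PTP1E_1	0.53	0.62	15	5
PTPN13_PTPL1_PTP1E_2	0.63	0.64	35	8
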