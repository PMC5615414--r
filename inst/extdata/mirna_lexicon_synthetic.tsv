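canonical_id	accession	aliases
miR-33	MIMAT9000001	
miR-33a	MIMAT9000002	
miR-33b	MIMAT9000003	
miR-144	MIMAT9000004	
miR-223	MIMAT9000005	
miR-185	MIMAT9000006	
miR-96	MIMAT9000007	
miR-103	MIMAT9000008	
miR-122	MIMAT9000009	
miR-122a	MIMAT9000010	
miR-17-92	MIMAT9000011	
miR-375	MIMAT9000012	
miR-200c	MIMAT9000013	
miR-126	MIMAT9000014	
miR-30c	MIMAT9000015	
miR-145	MIMAT9000016	
miR-29b	MIMAT9000017	
miR-155	MIMAT9000018	
miR-146a	MIMAT9000019	
miR-27b	MIMAT9000020	
miR-1	MIMAT9000021	
miR-1a-1	MIMAT9000022	
miR-15	MIMAT9000023	
miR-16	MIMAT9000024	
miR-221	MIMAT9000025	
miR-222	MIMAT9000026	
lin-4	MIMAT9000027	
let-7	MIMAT9000028	
let-7a	MIMAT9000029	
let-7b	MIMAT9000030	
miR-2	MIMAT9000031	
miR-3	MIMAT9000032	
miR-4	MIMAT9000033	
miR-5	MIMAT9000034	
miR-6	MIMAT9000035	
miR-7	MIMAT9000036	
miR-8	MIMAT9000037	
miR-9	MIMAT9000038	
miR-10	MIMAT9000039	
miR-11	MIMAT9000040	
miR-12	MIMAT9000041	
miR-13	MIMAT9000042	
miR-14	MIMAT9000043	
miR-18	MIMAT9000044	
miR-19	MIMAT9000045	
miR-20	MIMAT9000046	
miR-21	MIMAT9000047	
miR-22	MIMAT9000048	
miR-23	MIMAT9000049	
miR-24	MIMAT9000050	
miR-25	MIMAT9000051	
miR-26	MIMAT9000052	
miR-28	MIMAT9000053	
miR-31	MIMAT9000054	
miR-32	MIMAT9000055	
miR-34	MIMAT9000056	
miR-35	MIMAT9000057	
miR-36	MIMAT9000058	
miR-37	MIMAT9000059	
miR-38	MIMAT9000060	
miR-39	MIMAT9000061	
miR-40	MIMAT9000062	
miR-41	MIMAT9000063	
miR-42	MIMAT9000064	
miR-43	MIMAT9000065	
miR-44	MIMAT9000066	
miR-45	MIMAT9000067	
miR-46	MIMAT9000068	
miR-47	MIMAT9000069	
miR-48	MIMAT9000070	
miR-49	MIMAT9000071	
miR-50	MIMAT9000072	
miR-51	MIMAT9000073	
miR-52	MIMAT9000074	
miR-53	MIMAT9000075	
miR-54	MIMAT9000076	
miR-55	MIMAT9000077	
miR-56	MIMAT9000078	
miR-57	MIMAT9000079	
miR-58	MIMAT9000080	
miR-59	MIMAT9000081	
miR-60	MIMAT9000082	
miR-61	MIMAT9000083	
miR-62	MIMAT9000084	
miR-63	MIMAT9000085	
miR-64	MIMAT9000086	
miR-65	MIMAT9000087	
miR-66	MIMAT9000088	
miR-67	MIMAT9000089	
miR-68	MIMAT9000090	
miR-69	MIMAT9000091	
miR-70	MIMAT9000092	
miR-71	MIMAT9000093	
miR-72	MIMAT9000094	
miR-73	MIMAT9000095	
miR-74	MIMAT9000096	
miR-75	MIMAT9000097	
miR-76	MIMAT9000098	
miR-77	MIMAT9000099	
miR-78	MIMAT9000100	
miR-79	MIMAT9000101	
miR-80	MIMAT9000102	
miR-81	MIMAT9000103	
miR-82	MIMAT9000104	
miR-83	MIMAT9000105	
miR-84	MIMAT9000106	
miR-85	MIMAT9000107	
miR-86	MIMAT9000108	
miR-87	MIMAT9000109	
miR-88	MIMAT9000110	
miR-89	MIMAT9000111	
miR-90	MIMAT9000112	
miR-91	MIMAT9000113	
miR-92	MIMAT9000114	
miR-93	MIMAT9000115	
miR-94	MIMAT9000116	
miR-95	MIMAT9000117	
miR-97	MIMAT9000118	
miR-98	MIMAT9000119	
miR-99	MIMAT9000120	
miR-100	MIMAT9000121	
miR-101	MIMAT9000122	
miR-102	MIMAT9000123	
miR-104	MIMAT9000124	
miR-105	MIMAT9000125	
miR-106	MIMAT9000126	
miR-107	MIMAT9000127	
miR-108	MIMAT9000128	
miR-109	MIMAT9000129	
miR-110	MIMAT9000130	
miR-111	MIMAT9000131	
miR-112	MIMAT9000132	
miR-113	MIMAT9000133	
miR-114	MIMAT9000134	
miR-115	MIMAT9000135	
miR-116	MIMAT9000136	
miR-117	MIMAT9000137	
miR-118	MIMAT9000138	
miR-119	MIMAT9000139	
miR-120	MIMAT9000140	
miR-121	MIMAT9000141	
miR-123	MIMAT9000142	
miR-124	MIMAT9000143	
miR-125	MIMAT9000144	
miR-127	MIMAT9000145	
miR-128	MIMAT9000146	
miR-129	MIMAT9000147	
miR-130	MIMAT9000148	
miR-131	MIMAT9000149	
miR-132	MIMAT9000150	
miR-133	MIMAT9000151	
miR-134	MIMAT9000152	
miR-135	MIMAT9000153	
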