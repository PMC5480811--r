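gene	chrom	start	end	source
PHACTR1	chr6	12716894	13290103	published_text
FLT1	chr13	28300346	28495145	published_text
LPA	chr6	160531482	160664275	published_text
BCAS3	chr17	58418305	59133565	published_text
CNNM2	chr10	104678053	104838281	published_text
TEX41	chr2	145076899	145278109	published_text
SMG6	chr17	1963133	2207345	published_text
CADL08	chr21	52821679	53117224	synthetic
CADL09	chr8	177168240	177570113	synthetic
CADL10	chr4	1168966	1421526	synthetic
CADL11	chr22	73216317	73622894	synthetic
CADL12	chr2	171195303	171460955	synthetic
CADL13	chr10	85657366	86115455	synthetic
CADL14	chr9	155481318	155642705	synthetic
CADL15	chr2	162058302	162368375	synthetic
CADL16	chr2	162732090	163038296	synthetic
CADL17	chr15	170532554	170871737	synthetic
CADL18	chr16	80439291	80609045	synthetic
CADL19	chr3	116959668	117053457	synthetic
CADL20	chr3	184111776	184489090	synthetic
CADL21	chr4	79257935	79340720	synthetic
CADL22	chr6	3505427	3923840	synthetic
CADL23	chr4	137165239	137566876	synthetic
CADL24	chr9	58344398	58417057	synthetic
CADL25	chr7	21214151	21393083	synthetic
CADL26	chr8	181739573	182149113	synthetic
CADL27	chr3	123931957	124008083	synthetic
CADL28	chr14	82015059	82597494	synthetic
CADL29	chr11	132058766	132171930	synthetic
CADL30	chr17	157581431	157966228	synthetic
CADL31	chr11	181239353	181740953	synthetic
CADL32	chr18	123102837	123564675	synthetic
CADL33	chr1	156541776	156594128	synthetic
CADL34	chr14	191451072	191723006	synthetic
CADL35	chr7	141917132	141957580	synthetic
CADL36	chr7	156634067	156987555	synthetic
CADL37	chr9	9989871	10112386	synthetic
CADL38	chr22	121140163	121578605	synthetic
CADL39	chr6	182729460	183113242	synthetic
CADL40	chr19	22759688	22906720	synthetic
CADL41	chr21	25483441	25850889	synthetic
CADL42	chr5	132565398	133042044	synthetic
CADL43	chr13	137212198	137716816	synthetic
CADL44	chr8	12182833	12409224	synthetic
CADL45	chr15	131919403	132492045	synthetic
CADL46	chr14	152506051	152884542	synthetic
CADL47	chr18	42386815	42699225	synthetic
CADL48	chr3	113124660	113206395	synthetic
CADL49	chr2	28008860	28057097	synthetic
CADL50	chr18	9354211	9884659	synthetic
CADL51	chr7	93413928	93949470	synthetic
CADL52	chr4	86538649	86574429	synthetic
CADL53	chr7	36756322	36971708	synthetic
CADL54	chr12	108379691	108943116	synthetic
CADL55	chr21	179416523	179818716	synthetic
CADL56	chr3	151065356	151257496	synthetic
CADL57	chr2	88362888	88423118	synthetic
CADL58	chr17	29585082	30035804	synthetic
CADL59	chr3	61034156	61634152	synthetic
CADL60	chr9	135135570	135300532	synthetic
CADL61	chr19	96070792	96370194	synthetic
CADL62	chr19	62239265	62364842	synthetic
CADL63	chr6	53429799	53848711	synthetic
CADL64	chr10	25069691	25234146	synthetic
CADL65	chr2	80937848	81468210	synthetic
CADL66	chr2	86631418	86966835	synthetic
CADL67	chr17	2473546	2710134	synthetic
CADL68	chr18	199938834	200167275	synthetic
CADL69	chr7	175727724	175984258	synthetic
CADL70	chr3	172871963	173082799	synthetic
CADL71	chr10	69506246	69754644	synthetic
CADL72	chr7	25264198	25581280	synthetic
CADL73	chr21	167935146	168208560	synthetic
CADL74	chr18	25202536	25228002	synthetic
CADL75	chr12	168935880	169385089	synthetic
CADL76	chr7	105750408	105894463	synthetic
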