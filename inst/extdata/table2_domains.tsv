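gene	group	dbd_start	dbd_end	od_start	od_end	nls_pos	nls	nes_pos	nes	aha1_pos	aha1	aha2_pos	aha2
ZmHsf-01	A2	41	134	167	217	247	RKRRR	296	LENLALNI	336	DDFWEELLNE	NA	NA
ZmHsf-02	A9	48	140	180	230	254	NRKRR	NA	NA	NA	NA	NA	NA
ZmHsf-04	A2	43	136	168	218	233	KRK7KKRRR	344	LAQQLGYL	267	LKMFESGVLN	314	DDFWAELLVE
ZmHsf-05	A2	37	130	159	209	224	MRK7KKRRRR	NA	NA	314	DDFWEDLLHE	NA	NA
ZmHsf-06	A1	56	149	186	236	261	KKRR	505	IGDLTEQM	470	DSFWEQFL	NA	NA
ZmHsf-10	A6	137	232	263	313	337	KRQR	NA	NA	401	SDVWDELDLD	NA	NA
ZmHsf-12	A1	29	122	159	209	234	KKRR	477	LTEQM	436	NSIWEQFL	NA	NA
ZmHsf-14	A5	66	160	187	237	261	HKKRR	387	LNLSL	479	DKFWEQFLTE	NA	NA
ZmHsf-15	A3	73	166	193	243	267	KRKFLK	405	LSPLPDNMG	432	EQIWGVDASA	472	ERFWELDFQA
ZmHsf-16	A4	22	115	145	195	215	SKKRR	NA	NA	408	DVFWERFLTD	NA	NA
ZmHsf-17	A2	49	142	172	222	237	MRK7KKRRRR	359	LSEKMGYL	332	DNFWEQLLNE	NA	NA
ZmHsf-20	A4	10	103	133	183	203	SKKRR	NA	NA	387	DVFWERFLTD	NA	NA
ZmHsf-22	A4	7	100	130	180	197	GKKRR	155	MQELEDKLIF	368	DGFWQQFLTE	NA	NA
ZmHsf-23	A6	48	141	167	217	239	RKRR	257	LDIEELAM	291	DMIWYELLGE	324	AQPWAEMDE
ZmHsf-24	A9	48	141	180	230	254	NRKRR	NA	NA	NA	NA	NA	NA
ZmHsf-03	B	69	162	231	260	337	RKRMR	NA	NA	NA	NA	NA	NA
ZmHsf-07	B	19	113	226	255	276	RKK	369	LALECAGLSL	NA	NA	NA	NA
ZmHsf-08	B	15	108	175	203	259	RKRAR	206	VRQLDLGL	NA	NA	NA	NA
ZmHsf-11	B	34	127	199	228	297	RKRMR	NA	NA	NA	NA	NA	NA
ZmHsf-18	B	17	110	172	201	259	RKRGR	203	VRQLDLRL	NA	NA	NA	NA
ZmHsf-19	B	42	135	217	246	318	KRMR	NA	NA	NA	NA	NA	NA
ZmHsf-25	B	8	101	161	190	232	KRLR	279	LDVLTLSV	NA	NA	NA	NA
ZmHsf-09	C	24	117	171	207	224	KKRRR	NA	NA	NA	NA	NA	NA
ZmHsf-13	C	12	104	135	171	202	KRAR	NA	NA	NA	NA	NA	NA
ZmHsf-21	C	32	125	176	212	229	KKRRR	NA	NA	NA	NA	NA	NA
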