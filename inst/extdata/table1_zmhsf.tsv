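gene	translation	size_aa	mw_da	pi	chromosome
ZmHsf-01	GRMZM2G165972_P02	384	43268.46	5.30	1
ZmHsf-02	GRMZM2G118485_P02	417	46816.21	5.09	1
ZmHsf-03	GRMZM2G164909_P01	414	44382.81	6.80	1
ZmHsf-04	GRMZM2G010871_P01	357	40502.49	4.99	1
ZmHsf-05	GRMZM2G132971_P01	359	40587.23	5.57	1
ZmHsf-06	GRMZM2G115456_P01	527	56724.50	5.11	1
ZmHsf-07	GRMZM2G088242_P01	394	41742.83	7.81	2
ZmHsf-08	GRMZM2G002131_P01	298	32270.31	9.13	2
ZmHsf-09	GRMZM2G089525_P01	331	35883.69	5.94	3
ZmHsf-10	GRMZM2G005815_P01	462	50970.67	8.87	3
ZmHsf-11	GRMZM2G098696_P01	370	39562.03	5.89	4
ZmHsf-12	GRMZM2G384339_P01	497	54104.58	5.06	5
ZmHsf-13	GRMZM2G105348_P01	257	27836.98	5.85	5
ZmHsf-14	GRMZM2G179802_P02	528	58138.65	5.57	5
ZmHsf-15	GRMZM2G059851_P01	508	56061.66	4.96	5
ZmHsf-16	AC206165.3_FGP007	469	51623.79	5.41	6
ZmHsf-17	GRMZM2G125969_P01	375	42043.73	4.70	7
ZmHsf-18	GRMZM2G139535_P01	298	32258.35	9.53	7
ZmHsf-19	GRMZM2G165272_P01	394	41468.10	5.00	7
ZmHsf-20	AC205471.4_FGP003	446	49718.46	5.15	8
ZmHsf-21	GRMZM2G086880_P01	348	37409.50	8.09	8
ZmHsf-22	GRMZM2G118453_P01	433	48647.71	5.25	8
ZmHsf-23	GRMZM2G173090_P02	350	38154.66	4.95	9
ZmHsf-24	GRMZM2G026742_P01	407	45317.63	4.97	9
ZmHsf-25	GRMZM2G301485_P01	318	33947.51	5.70	10
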