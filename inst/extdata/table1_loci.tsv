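gene_id	chromosome	start	strand
ZmHsf-01	1	1	unknown
ZmHsf-02	1	2	unknown
ZmHsf-03	1	3	unknown
ZmHsf-04	1	4	unknown
ZmHsf-05	1	5	unknown
ZmHsf-06	1	6	unknown
ZmHsf-07	2	1	unknown
ZmHsf-08	2	2	unknown
ZmHsf-09	3	1	unknown
ZmHsf-10	3	2	unknown
ZmHsf-11	4	1	unknown
ZmHsf-12	5	1	unknown
ZmHsf-13	5	2	unknown
ZmHsf-14	5	3	unknown
ZmHsf-15	5	4	unknown
ZmHsf-16	6	1	unknown
ZmHsf-17	7	1	unknown
ZmHsf-18	7	2	unknown
ZmHsf-19	7	3	unknown
ZmHsf-20	8	1	unknown
ZmHsf-21	8	2	unknown
ZmHsf-22	8	3	unknown
ZmHsf-23	9	1	unknown
ZmHsf-24	9	2	unknown
ZmHsf-25	10	1	unknown
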