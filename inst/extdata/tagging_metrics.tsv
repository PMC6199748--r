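animal_id	tagging_date	tagging_lat	tagging_lon	duration_days	period
1995-3	1995-07-08	77.82	16.85	58	1995-2001
1995-2	1995-07-09	77.85	16.30	30	1995-2001
1995-1	1995-07-07	77.75	15.70	31	1995-2001
1996-1	1996-07-20	77.50	15.97	7	1995-2001
1997-1	1997-08-04	77.83	15.95	113	1995-2001
1997-2	1997-08-04	77.83	15.95	34	1995-2001
1997-3	1997-08-04	77.83	15.95	82	1995-2001
1998-7	1998-09-01	78.53	18.87	7	1995-2001
1999-4	1999-08-21	78.53	18.87	13	1995-2001
1999-3	1999-08-21	78.53	18.87	72	1995-2001
1999-5	1999-08-18	78.53	18.87	63	1995-2001
1999-6	1999-08-18	78.53	18.87	93	1995-2001
1999-7	1999-08-18	78.53	18.87	55	1995-2001
1999-8	1999-08-19	78.53	18.87	65	1995-2001
2000-2	2000-10-18	78.53	18.87	82	1995-2001
2001-1	2001-10-17	78.53	18.87	10	1995-2001
2001-2	2001-10-18	78.53	18.87	62	1995-2001
2001-3	2001-10-19	78.53	18.87	48	1995-2001
2013-1	2013-08-16	79.78	12.16	142	2013-2016
2013-2	2013-08-23	78.41	17.27	96	2013-2016
2013-3	2013-08-23	78.33	15.71	82	2013-2016
2014-8	2014-08-18	77.49	14.66	21	2013-2016
2014-3	2014-08-14	76.98	16.37	127	2013-2016
2014-2	2014-08-14	76.98	16.37	51	2013-2016
2014-5	2014-08-11	76.98	16.37	126	2013-2016
2014-1	2014-08-11	76.98	16.37	20	2013-2016
2014-4	2014-08-03	78.53	18.87	118	2013-2016
2015-5	2015-07-19	79.32	11.72	19	2013-2016
2015-8	2015-07-19	79.15	11.62	2	2013-2016
2016-5	2016-08-04	78.03	14.13	107	2013-2016
2016-3	2016-08-09	78.04	14.22	163	2013-2016
2016-4	2016-07-19	78.45	11.68	56	2013-2016
2016-2	2016-08-04	78.05	14.01	115	2013-2016
2016-1	2016-08-14	78.38	17.03	146	2013-2016
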