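shark_id,tag_date,sex,tl_cm,days_detected,days_monitored,residency_index,years_returned,max_years_monitored
1,2009-03-04,Male,282,28,2277,0.01,0,6
2,2009-03-24,Male,247,32,2257,0.01,4,6
3,2010-01-21,Male,276,380,1954,0.19,4,5
4,2010-01-21,Male,257,256,1954,0.13,5,5
5,2010-01-25,Male,235,13,1950,0.01,5,5
6,2010-02-08,Male,240,137,1936,0.07,5,5
7,2010-02-11,Male,264,144,1933,0.07,5,5
8,2010-02-17,Male,220,300,1927,0.16,5,5
9,2010-02-24,Male,276,181,1920,0.09,5,5
10,2010-03-02,Male,273,368,1914,0.19,5,5
11,2010-03-03,Male,288,9,1913,0.00,0,5
12,2011-01-11,Female,322,1,1599,0.00,0,4
13,2011-01-11,Male,282,34,1599,0.02,2,4
14,2011-01-11,Male,296,49,1599,0.03,3,4
15,2011-01-19,Male,306,23,1591,0.01,3,4
16,2011-01-19,Female,286,1,1591,0.00,0,4
17,2011-01-25,Male,312,3,1585,0.00,0,4
18,2011-01-27,Female,251,29,1583,0.02,0,4
19,2011-02-01,Male,260,60,1578,0.04,4,4
20,2011-02-04,Female,264,121,1575,0.08,3,4
21,2011-02-12,Male,288,38,1567,0.02,2,4
22,2011-02-12,Female,274,4,1567,0.00,1,4
23,2011-02-21,Male,272,121,1558,0.08,2,4
24,2011-03-03,Female,296,68,1548,0.04,2,4
25,2011-03-08,Male,293,160,1543,0.10,3,4
26,2011-03-11,Male,228,1,1540,0.00,0,4
27,2011-04-06,Male,296,4,1514,0.00,0,3
28,2012-01-09,Female,294,24,1236,0.02,1,3
29,2012-01-18,Female,301,17,1227,0.01,1,3
30,2012-01-24,Female,274,13,1221,0.01,1,3
31,2012-01-25,Female,247,70,1220,0.06,3,3
32,2012-01-30,Male,260,1,1215,0.00,0,3
33,2012-01-31,Male,234,26,1214,0.02,0,3
34,2012-01-31,Male,258,18,1214,0.01,1,3
35,2013-01-16,Female,264,61,863,0.07,1,2
36,2013-01-16,Male,279,27,863,0.03,0,2
37,2013-01-17,Male,270,9,862,0.01,2,2
38,2013-01-17,Male,248,92,862,0.11,1,2
39,2013-01-17,Male,275,41,862,0.05,2,2
40,2013-01-30,Female,220,21,849,0.02,0,2
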