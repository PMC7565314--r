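sample,row_type,infection,age_years,copies_16s,ill_raw_reads,ill_pct_classified,ill_genera_1pct,ill_isi,np_raw_reads,np_pct_classified,np_genera_1pct,np_isi,below_cutoff_mark
1,patient,yes,3.50,5e+05,133880,92,5,4.2,34944,77,5,3.0,no
2,patient,yes,0.92,1e+05,186250,95,5,1.9,15254,79,3,2.2,no
3,patient,yes,2.00,3e+05,1661,94,5,4.1,39474,77,4,2.9,no
4,patient,yes,1.50,3e+05,154877,96,7,4.6,36608,76,6,2.3,no
5,patient,yes,9.00,3e+05,114702,97,5,3.5,5107,59,4,2.7,no
6,patient,yes,2.00,3e+05,22805,97,5,2.7,31642,52,4,1.7,no
7,patient,yes,5.00,2e+05,1940,88,8,3.8,2246,57,6,3.1,no
8,patient,yes,4.00,3e+05,24214,100,4,1.2,10174,62,3,1.2,no
9,patient,yes,1.67,4e+05,104134,93,9,2.5,21462,68,6,2.6,no
10,patient,yes,8.00,2e+05,186945,96,3,2.5,923,68,2,1.6,no
11,patient,yes,11.00,2e+05,120867,95,3,3.0,27569,78,3,1.6,no
12,patient,yes,0.42,4e+05,25743,98,3,3.0,5127,66,3,2.2,no
13,patient,yes,15.00,4e+05,261123,95,4,2.7,12572,66,5,2.0,no
14,patient,yes,2.17,1e+05,6246,97,4,3.0,20441,89,3,2.7,no
15,patient,yes,3.80,3e+05,68095,91,3,2.3,27077,90,4,2.5,no
16,patient,yes,2.40,1e+05,119295,84,7,2.9,2978,85,6,2.6,no
17,patient,yes,0.80,2e+05,74902,96,3,1.5,4408,91,2,1.1,no
18,patient,yes,61.00,3e+03,77851,86,6,3.4,2141,82,8,4.1,no
19,patient,yes,0.90,3e+05,74730,85,4,2.3,20584,82,6,1.6,no
20,patient,yes,0.80,3e+05,113078,93,3,2.4,10974,91,3,1.9,no
21,patient,yes,78.00,2e+05,131837,90,2,1.7,21449,93,1,1.0,no
22,patient,yes,1.70,3e+05,162890,85,4,2.4,23530,92,5,1.8,no
23,patient,yes,2.30,2e+05,83596,92,8,4.4,15748,88,7,3.2,no
24,patient,yes,73.00,2e+05,83947,84,4,2.0,3181,88,5,3.3,no
25,patient,yes,2.60,5e+05,28221,92,3,3.0,15453,50,3,3.1,no
26,patient,yes,65.00,3e+05,77012,82,7,4.5,31461,85,6,2.8,no
27,patient,yes,0.80,1e+05,58962,85,3,2.5,23652,90,3,1.5,no
28,patient,yes,3.00,5e+05,57600,86,6,3.7,22991,84,7,3.4,no
29,patient,yes,57.00,2e+05,129131,94,2,1.5,48167,90,1,1.1,no
30,patient,yes,0.40,6e+05,180796,88,3,2.9,3997,65,4,2.3,no
31,patient,yes,0.90,4e+05,547695,98,4,2.7,15626,80,7,1.7,no
32,patient,yes,23.00,8e+05,750669,97,3,1.8,6653,67,2,1.6,no
33,patient,yes,3.40,1e+05,924890,98,7,3.3,25148,74,7,2.1,no
34,patient,yes,4.10,1e+06,31896,94,5,4.0,15979,49,4,2.7,no
35,patient,yes,14.00,3e+05,79970,90,3,2.1,40551,88,3,1.4,no
36,patient,yes,0.10,3e+05,113047,88,3,1.7,50,76,NA,NA,no
37,patient,yes,0.40,3e+05,59397,88,4,2.9,51254,63,11,3.6,yes
38,patient,yes,0.30,6e+05,7421,99,3,1.4,41757,89,2,1.4,no
39,patient,yes,1.10,3e+05,121819,86,3,2.6,6340,86,6,1.9,no
40,patient,yes,0.20,2e+05,83457,83,4,2.4,59923,82,6,1.9,no
41,patient,yes,4.20,4e+05,92006,87,4,2.9,17785,90,4,2.3,no
42,patient,yes,0.10,1e+05,36248,90,4,2.0,45047,92,3,1.9,no
43,patient,yes,0.10,2e+05,55585,92,5,2.3,47084,92,3,1.4,no
44,patient,yes,0.40,3e+05,101465,87,5,2.7,5288,80,6,1.6,no
45,patient,yes,1.70,7e+05,92476,89,3,1.9,49104,55,2,1.1,no
46,patient,yes,0.50,3e+05,72068,88,4,2.1,50486,80,6,1.5,no
47,patient,yes,0.10,5e+05,90128,80,6,4.0,107161,91,6,3.2,no
48,patient,yes,67.00,2e+05,51826,94,5,1.3,8,75,NA,NA,yes
49,patient,yes,0.30,9e+05,1148,82,8,4.3,14673,66,3,1.5,no
50,patient,yes,3.30,5e+06,39030,83,3,2.6,12239,66,3,2.0,no
51,patient,yes,56.00,5e+06,2191,85,7,3.3,17248,64,7,2.4,no
52,patient,no,28.00,3e+05,193859,96,2,1.2,6789,91,1,1.0,no
53,patient,no,62.00,2e+05,262184,89,3,2.3,18680,88,2,1.8,no
54,patient,no,8.10,2e+05,308123,83,5,2.8,13741,89,4,2.3,no
55,patient,no,7.20,3e+05,203242,100,6,3.4,15490,84,6,4.3,no
56,patient,no,14.90,1e+05,235820,92,3,1.4,18318,88,8,5.0,no
57,patient,no,5.40,9e+05,90422,86,3,2.8,11207,87,4,2.2,no
58,patient,no,7.10,6e+05,103176,87,5,2.9,19604,73,7,2.7,no
59,patient,no,6.40,1e+05,111844,93,4,1.6,17971,88,3,1.1,no
Average,average,NA,12.5,8e+05,131024,91,4.4,2.7,21907,78,4.5,2.2,no
C-1,control,NA,NA,<1e+02,6,0,0,NA,7,57,4,NA,no
C-2,control,NA,NA,<1e+02,1,0,0,0,42,74,8,NA,no
C-3,control,NA,NA,<1e+02,1,0,0,0,33,42,9,NA,no
C-4,control,NA,NA,<1e+02,3,0,0,0,35,51,11,NA,no
C-5,control,NA,NA,<1e+02,2,0,0,0,15,67,3,NA,no
C-6,control,NA,NA,2e+02,2440,98,4,4,56,91,6,NA,no
C-7,control,NA,NA,3e+02,3408,94,18,18,0,0,0,NA,no
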