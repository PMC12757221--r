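rank,atc_code,drug,cases,ror,ror_lo,ror_hi,prr,chi2,ebgm,ebgm05,ic,ic025
1,L01BB02,Mercaptopurine,67,26.57,20.84,33.89,25.89,1599.01,25.8,21.05,4.69,4.33
2,L01XX24,Pegaspargase,60,13.67,10.59,17.64,13.49,692.46,13.45,10.87,3.75,3.38
3,L01FX07,Blinatumomab,85,11.93,9.63,14.78,11.8,837.18,11.75,9.82,3.55,3.24
4,L02BG04,Letrozole,221,11.01,9.63,12.58,10.9,1965.08,10.78,9.64,3.43,3.23
5,L01EA02,Dasatinib,299,10.25,9.14,11.5,10.16,2431.52,10.01,9.09,3.32,3.15
6,L01EF02,Ribociclib,141,8.42,7.13,9.94,8.36,907.11,8.3,7.22,3.05,2.81
7,L01EF03,Abemaciclib,86,7.3,5.9,9.03,7.25,461.7,7.22,6.04,2.85,2.54
8,L01EX03,Pazopanib,174,7.05,6.07,8.19,7.01,888.74,6.95,6.13,2.8,2.58
9,L01EC01,Vemurafenib,65,6.87,5.38,8.77,6.82,322.34,6.8,5.55,2.77,2.41
10,L01BC01,Cytarabine,74,6.13,4.88,7.71,6.1,314.5,6.08,5.02,2.6,2.27
11,L01DB01,Doxorubicin,198,6.06,5.27,6.98,6.03,823.4,5.98,5.32,2.58,2.37
12,L01BA01,Methotrexate,766,6.01,5.59,6.46,5.98,3052.02,5.78,5.44,2.53,2.42
13,L01EC02,Dabrafenib,72,5.49,4.35,6.92,5.46,261.75,5.45,4.48,2.45,2.11
14,L01FF02,Pembrolizumab,245,5.23,4.61,5.93,5.2,822.33,5.15,4.63,2.36,2.18
15,L01FX04,Ipilimumab,91,5.15,4.19,6.34,5.13,301.66,5.11,4.3,2.35,2.05
16,L01EH01,Lapatinib,62,5.04,3.92,6.47,5.01,198.84,5,4.06,2.32,1.96
17,L01FF05,Atezolizumab,106,4.87,4.02,5.9,4.85,322.47,4.83,4.11,2.27,1.99
18,L01BA04,Pemetrexed,61,4.81,3.74,6.19,4.79,182.52,4.78,3.87,2.26,1.89
19,L01FD01,Trastuzumab,146,4.31,3.66,5.08,4.3,367.19,4.27,3.73,2.1,1.86
20,L01EK01,Axitinib,54,3.53,2.7,4.62,3.52,97.39,3.52,2.81,1.81,1.42
21,L01XA02,Carboplatin,147,3.39,2.88,3.99,3.38,245.11,3.36,2.94,1.75,1.51
22,L01EX09,Nintedanib,71,3.35,2.66,4.24,3.35,116.47,3.34,2.75,1.74,1.4
23,L01AA01,Cyclophosphamide,97,3.2,2.62,3.91,3.19,145.54,3.18,2.69,1.67,1.38
24,L01FA01,Rituximab,306,3.15,2.82,3.53,3.15,441.13,3.11,2.83,1.64,1.47
25,L01EA01,Imatinib,176,3.06,2.64,3.55,3.05,240.84,3.03,2.68,1.6,1.38
26,L04AC07,Tocilizumab,176,3.06,2.64,3.55,3.06,241.4,3.04,2.68,1.6,1.38
27,L01CD01,Paclitaxel,108,2.98,2.46,3.6,2.97,140.47,2.96,2.53,1.57,1.29
28,L01BC05,Gemcitabine,78,2.92,2.34,3.65,2.92,97.95,2.91,2.41,1.54,1.21
29,L01FF01,Nivolumab,188,2.89,2.5,3.33,2.88,228.65,2.86,2.54,1.52,1.31
30,L01XA03,Oxaliplatin,88,2.76,2.24,3.4,2.75,98.03,2.75,2.3,1.46,1.15
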