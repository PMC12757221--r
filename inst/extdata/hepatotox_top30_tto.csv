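sn,drug,cases,tto_median,tto_q1,tto_q3,alpha,alpha_lo,alpha_hi,beta,beta_lo,beta_hi,failure_type
1,Mercaptopurine,67,72,10.5,315,235.14,17.16,453.11,0.43,0.31,0.55,early
2,Pegaspargase,60,1,1,7.5,4.66,-2.33,11.64,0.80,0.11,1.50,random
3,Blinatumomab,85,4,1,10,11.30,-0.87,23.46,0.54,0.34,0.74,early
4,Letrozole,221,51,27.5,91,86.35,64.58,108.12,0.93,0.78,1.07,random
5,Dasatinib,299,64,36,94.5,68.87,-1.38,139.12,1.16,0.03,2.29,random
6,Ribociclib,141,26,10.5,114.5,70.14,-9.90,150.19,0.69,0.30,1.08,random
7,Abemaciclib,86,60,21,84,76.99,16.45,137.53,0.88,0.45,1.31,random
8,Pazopanib,174,40.5,21,49,49.52,30.08,68.97,1.13,0.81,1.44,random
9,Vemurafenib,65,43.5,12,56.25,48.53,19.13,77.92,1.08,0.57,1.59,random
10,Cytarabine,74,15,12,15,15.77,10.28,21.26,2.64,0.77,4.52,random
11,Doxorubicin,198,1,NA,NA,NA,NA,NA,NA,NA,NA,NA
12,Methotrexate,766,72,10.5,315,235.14,17.16,453.11,0.43,0.31,0.55,early
13,Dabrafenib,72,107,58,195,184.32,83.89,284.74,0.93,0.61,1.24,random
14,Pembrolizumab,245,50.5,21,71.75,73.55,36.59,110.50,0.84,0.61,1.08,random
15,Ipilimumab,91,44,22,96,82.92,41.31,124.52,0.91,0.63,1.18,random
16,Lapatinib,62,42,36,91,77.21,48.73,105.70,1.46,0.91,2.01,random
17,Atezolizumab,106,27,19.5,112.5,74.98,37.45,112.50,0.75,0.55,0.94,early
18,Pemetrexed,61,41,41,41,45.17,37.09,53.25,3.10,1.94,4.26,wear_out
19,Trastuzumab,146,49,23,101,212.76,32.21,393.31,0.54,0.37,0.71,early
20,Axitinib,54,19,11.5,37,27.13,-1.67,55.93,1.12,0.09,2.16,random
21,Carboplatin,147,45,31,78.5,63.91,40.60,87.23,1.17,0.78,1.56,random
22,Nintedanib,71,9.5,3.5,71,33.34,-13.08,79.77,0.61,0.23,0.99,early
23,Cyclophosphamide,97,37,16,63,39.10,-8.55,86.75,0.84,0.12,1.55,random
24,Rituximab,306,25,9,39,48.73,-13.87,111.34,0.61,0.28,0.94,early
25,Imatinib,176,75.5,53.75,87.75,73.85,37.88,109.82,2.09,0.23,3.95,random
26,Tocilizumab,176,18,7.25,40.75,29.90,-1.40,61.20,0.99,0.24,1.75,random
27,Paclitaxel,108,56,32,73,55.94,42.16,69.72,1.82,1.18,2.46,wear_out
28,Gemcitabine,78,19.5,5.5,54.5,35.06,-11.22,81.33,0.79,0.19,1.39,random
29,Nivolumab,188,47.5,20.25,71,68.38,50.14,86.61,1.06,0.85,1.27,random
30,Oxaliplatin,88,10.5,4,14,16.36,3.01,29.71,0.90,0.46,1.35,random
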