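start_ma,end_ma,fossil,autohard,autosoft,irhard,irsoft
5,0,1.39E-01,2.11E-02,2.98E-01,-3.63E-04,-2.95E-01
10,5,2.86E-02,2.68E-01,5.91E-02,2.71E-01,2.98E-01
15,10,4.84E-02,1.64E-02,6.60E-02,4.41E-04,-2.23E-01
20,15,1.65E-01,8.00E-02,8.01E-05,6.94E-02,2.10E-01
25,20,1.25E-01,4.19E-02,1.03E-02,5.66E-02,-2.95E-04
30,25,-1.14E-01,2.03E-02,8.68E-04,1.60E-02,-1.11E-01
35,30,-5.34E-02,5.97E-02,3.35E-03,2.08E-01,1.29E-01
40,35,-1.96E-03,1.24E-02,7.52E-03,1.89E-01,2.23E-06
45,40,-1.28E-02,9.16E-02,8.03E-04,1.70E-01,6.34E-02
50,45,1.36E-02,1.01E-06,6.64E-03,1.76E-01,1.07E-01
55,50,2.25E-01,1.64E-01,1.43E-03,2.15E-01,4.54E-02
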