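age_y,sex,bw_kg,ht_cm,blood_ml,hct,co_l_min,ecw_scale
0,male,3.5,51,290,0.47,0.60,1.55
0.25,male,6.0,61,470,0.35,1.00,1.45
0.5,male,7.9,67,610,0.35,1.20,1.40
1,male,10.0,76,780,0.36,1.40,1.32
2,male,12.5,87,950,0.37,1.75,1.25
5,male,19.0,109,1400,0.38,2.50,1.15
10,male,32.0,138,2400,0.40,3.80,1.08
15,male,56.0,167,4200,0.42,5.50,1.02
25,male,73.0,176,5300,0.44,6.50,1.00
35,male,73.0,176,5300,0.44,6.50,1.00
60,male,73.0,176,5200,0.44,6.20,1.00
80,male,70.0,174,5000,0.44,5.80,1.00
0,female,3.3,51,270,0.47,0.55,1.55
0.25,female,5.5,60,440,0.35,0.95,1.45
0.5,female,7.3,66,560,0.35,1.10,1.40
1,female,9.2,74,720,0.36,1.30,1.32
2,female,12.0,86,900,0.37,1.65,1.25
5,female,18.0,108,1300,0.38,2.40,1.15
10,female,32.0,138,2300,0.39,3.60,1.08
15,female,53.0,162,3600,0.40,5.00,1.02
25,female,60.0,163,3900,0.40,5.90,1.00
35,female,60.0,163,3900,0.40,5.90,1.00
60,female,60.0,162,3900,0.40,5.60,1.00
80,female,58.0,160,3700,0.40,5.30,1.00
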