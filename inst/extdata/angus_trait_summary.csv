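trait,units,h2,n_bulls,mean_reliability,var_p,var_g,acc_kmeans,slope_kmeans,acc_random,slope_random
Birth weight,kg,0.42,3203,0.79,20.63,8.67,0.554,0.879,0.700,0.953
Calving ease direct,%,0.18,3180,0.62,825.05,148.51,0.488,0.942,0.617,1.007
Calving ease maternal,%,0.12,1965,0.59,1313.37,157.6,0.416,1.181,0.571,1.277
Carcass weight,kg,0.40,2448,0.41,1535.06,614.03,0.471,1.130,0.689,1.208
Docility,%,0.37,1363,0.50,1634.60,604.8,0.218,0.614,0.490,1.150
Fat thickness,mm,0.34,3155,0.40,4.8,1.63,0.603,1.113,0.793,1.211
Heifer pregnancy rate,%,0.13,698,0.48,1031.74,134.13,0.269,1.337,0.378,1.580
Marbling,units,0.45,3199,0.44,0.797,0.359,0.690,1.058,0.817,1.041
Maternal weaning weight,kg,0.14,2066,0.70,1160.85,162.52,0.318,0.702,0.492,0.829
Mature height,mm,0.82,1290,0.64,494.03,405.13,0.359,0.977,0.819,1.091
Mature weight,kg,0.55,1320,0.64,4638.66,2551.28,0.312,0.898,0.769,1.125
Rib eye muscle area,mm2,0.51,3231,0.47,430.32,219.35,0.601,0.993,0.694,0.958
Scrotal circumference,mm,0.43,2464,0.69,839.98,361.19,0.487,0.916,0.600,0.983
Weaning weight,kg,0.20,3191,0.69,1558.04,311.61,0.333,0.597,0.534,0.760
Yearling height,mm,0.45,2239,0.70,344.68,155.19,0.575,1.015,0.850,1.011
Yearling weight,kg,0.49,2755,0.69,2049.19,1004.12,0.356,0.642,0.573,0.790
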