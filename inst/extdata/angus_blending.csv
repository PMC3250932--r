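trait,b1,b2,cor_pa_dgv
Birth weight,0.66,0.54,0.41
Calving ease direct,0.38,0.80,0.51
Calving ease maternal,0.13,1.09,0.45
Carcass weight,-0.19,1.20,0.51
Docility,0.82,0.17,0.27
Fat thickness,0.03,1.10,0.54
Heifer pregnancy rate,0.23,1.09,0.40
Marbling,0.17,0.97,0.65
Maternal weaning weight,0.69,0.42,0.60
Mature height,0.21,0.81,0.48
Mature weight,0.04,0.87,0.37
Rib eye muscle area,0.24,0.89,0.61
Scrotal circumference,0.49,0.60,0.54
Weaning weight,0.50,0.42,0.38
Yearling height,0.70,0.56,0.47
Yearling weight,0.54,0.46,0.46
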