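diet,temp_C,rel_humidity,window_hours,f_carb,f_protein,f_fat,food_d18O,food_cap17O,cell_corn_d18O,cell_wheat_d18O,cell_soy_d18O,w_corn,w_wheat,w_soy
0.49,25,0.45,96,0.672,0.254,0.074,-18.16,30,26,26.9,25.9,0.43,0.37,0.20
0.49,18,0.60,96,0.672,0.254,0.074,-16.41,30,26,26.9,25.9,0.43,0.37,0.20
0.49,15,0.68,96,0.672,0.254,0.074,-16.35,30,26,26.9,25.9,0.43,0.37,0.20
4,25,0.45,48,0.658,0.265,0.077,-16.41,30,26,26.9,25.9,0.39,0.39,0.22
4,18,0.60,48,0.658,0.265,0.077,-16.41,30,26,26.9,25.9,0.39,0.39,0.22
4,15,0.68,48,0.658,0.265,0.077,-16.35,30,26,26.9,25.9,0.39,0.39,0.22
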