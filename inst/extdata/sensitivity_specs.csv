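parameter,label,base,low,high,printed_d18O_change,printed_cap17O_change,printed_d18O_rank,printed_cap17O_rank
faecal_water_fraction,faecal H2O content,0.55,0.30,0.90,0.00,0,21,26
ouf,oxygen utilization fraction,0.25,0.05,0.45,1.70,38,8,2
z_value_permil,z-value (permil),10.5,4,12,3.01,40,2,1
body_temp_C,body temperature (C),38,34,40,0.50,1,14,24
meeh_k,Meeh factor,1100,900,1300,0.31,0,16,26
skin_evap_rate,skin H2O evaporation rate,0.025,0.001,0.1,5.12,4,1,13
rel_humidity,relative humidity,0.45,0,1,2.29,2,4,17
ambient_temp_C,environmental temperature (C),25,0,40,1.35,2,10,16
preformed_water.d18O_permil,pre-formed water d18O,-4,0,-6,1.63,7,9,11
preformed_water.cap17O_permeg,pre-formed water 17O-excess,20,0,40,0,12,21,8
atmospheric_O2.d18O_permil,atmospheric O2 d18O,24.046,20,27,1.87,9,6,10
atmospheric_O2.cap17O_permeg,atmospheric O2 17O-excess,-441,-520,-360,0,29,21,4
digestibility,relative digestibility,0.85,0.40,0.90,2.88,2,3,17
water_leakage,water nozzle leakage,0.10,0,0.30,0.39,11,15,9
energy_extraction,energy extraction efficiency,1.0,0.80,1.0,1.02,1,11,25
food_water_content,food free H2O content,0.09,0,0.25,1.72,5,7,12
food_free_water.d18O_permil,food d18O,-16.41,-25,0,0.82,4,12,14
food_free_water.cap17O_permeg,food 17O-excess,30,0,50,0,1,21,23
cellulose.corn,cellulose d18O corn,26,22,30,0.27,2,18,20
cellulose.wheat,cellulose d18O wheat,26.9,22,30,0.31,2,16,17
cellulose.soybean,cellulose d18O soybean,25.9,22,30,0.22,2,19,22
theta.co2,theta exhaled CO2 - body water,0.5248,0.522,0.526,0,32,21,3
theta.bound_oxygen,theta cellulose - pre-formed water,0.525,0.525,0.530,0,28,21,5
theta.transcutaneous,theta transcutaneous loss - body water,0.5235,0.516,0.525,0,13,21,7
alpha18_transcutaneous,alpha18 transcutaneous loss - body water,0.982,0.976,0.990,0.74,2,13,21
theta.oxidase,theta lung-absorbed O2 - atmospheric O2,0.5179,0.5166,0.519,0,3,21,15
alpha18_oxidase,alpha18 lung-absorbed O2 - atmospheric O2,0.994,0.99,1,2.07,27,5,6
oral_nasal_split,oral/nasal split of exhaled vapour,0.5,0.0625,0.4375,0.02,0,20,26
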