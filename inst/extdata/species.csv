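name,mass_kg,body_length_m,body_width_m,mean_group_size
chital,65,1.55,0.6,8.15
gaur,825,3.3,1,4.75
leopard,49.25,2.43,0.4,1
sambar,202.5,2.1,0.8,2.85
tiger,173.75,3.1,0.6,1
wild_pig,90,2,0.5,5.87
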