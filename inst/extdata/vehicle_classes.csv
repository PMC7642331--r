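class,length_m,width_m,free_speed_mean_kmh,free_speed_sd_kmh
car,4.0,1.8,80,10
bus_truck,10.3,2.5,65,8
mav,14.0,2.6,55,6
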