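id,magnification,na,field_number_um,n_immersion,immersion
4x/0.13-air,4,0.13,26500,1.0,air
10x/0.3-air,10,0.3,26500,1.0,air
20x/0.5-air,20,0.5,26500,1.0,air
20x/0.75-air,20,0.75,26500,1.0,air
25x/1.1-water,25,1.1,22000,1.33,water
40x/0.95-air,40,0.95,26500,1.0,air
40x/1.15-water,40,1.15,22000,1.33,water
60x/1.2-water,60,1.2,22000,1.33,water
60x/1.4-oil,60,1.4,22000,1.52,oil
60x/1.49-oil,60,1.49,22000,1.52,oil
100x/1.45-oil,100,1.45,22000,1.52,oil
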