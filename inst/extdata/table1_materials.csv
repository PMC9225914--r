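# Material parameters of the three biological tissue layers:
# specific heat Cp (J kg^-1 K^-1), density rho (kg m^-3),
# thermal conductivity k (W m^-1 K^-1).
tissue,specific_heat,density,conductivity
Skin,3391,1109,0.37
Fat,2348,911,0.21
Muscle,3421,1090,0.49
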