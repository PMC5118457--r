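gas,temperature_C,solubility_mol_L_bar
CO2,25,0.0334
CO2,38,0.0243
O2,25,0.00126
O2,38,0.00102
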