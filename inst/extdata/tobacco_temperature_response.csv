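parameter,variant,value_25C,unit,dHa_kJ_mol
Kc,cc_basis,27.238,Pa,80.99
Ko,cc_basis,16.582,kPa,23.72
gammastar,cc_basis,3.743,Pa,24.46
Kc,ci_basis,40.49,Pa,79.43
Ko,ci_basis,27.84,kPa,36.38
gammastar,ci_basis,4.275,Pa,37.83
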