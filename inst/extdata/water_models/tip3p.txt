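# Rigid three-site water model (TIP3P-like).
# Units: Angstrom, elementary charge, kJ/mol. rho0 in A^-3.
# site <name> <kind> <x> <y> <z> <charge> <sigma> <epsilon>
name TIP3P
rho0 0.0329
site O  water_oxygen    0.000000 0.000000 0.000000 -0.834 3.15061 0.63639
site H1 water_hydrogen  0.756950 0.585882 0.000000  0.417 0.00000 0.00000
site H2 water_hydrogen -0.756950 0.585882 0.000000  0.417 0.00000 0.00000
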