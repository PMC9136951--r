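# Rigid four-site water model (TIP4P-like); M is a massless charge site.
# Units: Angstrom, elementary charge, kJ/mol. rho0 in A^-3.
# site <name> <kind> <x> <y> <z> <charge> <sigma> <epsilon>
name TIP4P
rho0 0.0332
site O  water_oxygen    0.000000 0.000000 0.000000  0.000 3.15365 0.64852
site M  water_virtual   0.000000 0.150000 0.000000 -1.040 0.00000 0.00000
site H1 water_hydrogen  0.756950 0.585882 0.000000  0.520 0.00000 0.00000
site H2 water_hydrogen -0.756950 0.585882 0.000000  0.520 0.00000 0.00000
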