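# fsvqe molecular integral fixture v1
molecule H2
basis_label STO-3G
geometry_id 2
n_spin_orbitals 4
n_electrons 2
e_nuclear 0.26458860545150004
hf_energy -0.78379265426414491
one_body 4 4
-0.77892203606895061 0 -1.4311020586438057e-17 0 0 -0.77892203606895061
0 -1.4311020586438057e-17 1.0210702003828474e-16 0 -0.67026667182753841 0
0 1.0210702003828474e-16 0 -0.67026667182753841
two_body 4 4 4 4
0.50946281242225622 0 0 0 0 0
0 0 0 0 0.2591384748844569 0
0 0 0 0 0 0.50946281242225622
0 0 0 0 0 0
0 0 0 0.2591384748844569 0 0
0 0 0 0 0.51920125812541351 0
0 0 0 0 0.2591384748844569 0
0 0 0 0 0 0
0 0 0 0.51920125812541351 0 0
0 0 0 0.2591384748844569 0 0
0 0 0 0 0 0
0 0 0.50946281242225622 0 0 0
0 0 0 0 0 0
0.2591384748844569 0 0 0 0 0
0 0.50946281242225622 0 0 0 0
0 0 0 0 0 0.2591384748844569
0 0 0 0 0 0
0.51920125812541351 0 0 0 0 0
0.2591384748844569 0 0 0 0 0
0 0 0 0 0 0.51920125812541351
0 0 0 0 0 0.2591384748844569
0 0 0 0 0.2591384748844569 0
0 0 0 0 0.51920125812541362 0
0 0 0 0 0 0
0 0 0 0.2591384748844569 0 0
0 0 0 0.51920125812541362 0 0
0 0 0 0 0.2591384748844569 0
0 0 0 0 0 0
0 0 0.53466411952427584 0 0 0
0 0 0 0.2591384748844569 0 0
0 0 0 0 0 0
0 0.53466411952427584 0 0 0 0
0 0 0 0 0 0
0.2591384748844569 0 0 0 0 0
0.51920125812541362 0 0 0 0 0
0 0 0 0 0 0.2591384748844569
0 0 0 0 0 0.51920125812541362
0 0 0 0 0 0
0.2591384748844569 0 0 0 0 0
0 0 0 0 0.53466411952427584 0
0 0 0 0 0 0.2591384748844569
0 0 0 0 0 0
0 0 0 0.53466411952427584
mo_coefficients 2 2
0.66838692323393079 0.66838692323393079 -0.7534430379286694 0.7534430379286694
overlap 2 2
1 0.11921652907137766 0.11921652907137766 1
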