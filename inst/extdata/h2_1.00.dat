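# fsvqe molecular integral fixture v1
molecule H2
basis_label STO-3G
geometry_id 1
n_spin_orbitals 4
n_electrons 2
e_nuclear 0.52917721090300007
hf_energy -1.0661086493089349
one_body 4 4
-1.110844179867877 0 -1.0413825129492708e-16 0 0 -1.110844179867877
0 -1.0413825129492708e-16 -1.3078976015254099e-16 0 -0.58912100371555831 0
0 -1.3078976015254099e-16 0 -0.58912100371555831
two_body 4 4 4 4
0.62640249952381899 0 2.7755575615628914e-17 0 0 0
0 0 5.5511151231257827e-17 0 0.19679058348750939 0
0 0 0 0 0 0.62640249952381899
0 2.7755575615628914e-17 0 0 0 0
0 5.5511151231257827e-17 0 0.19679058348750939 0 0
0 0 4.163336342344337e-17 0 0.62170676311493134 0
0 0 0 0 0.19679058348750939 0
2.7755575615628914e-17 0 0 0 0 0
0 4.163336342344337e-17 0 0.62170676311493134 0 0
0 0 0 0.19679058348750939 0 2.7755575615628914e-17
0 0 0 0 0 0
0 0 0.62640249952381899 0 2.7755575615628914e-17 0
0 0 0 0 5.5511151231257827e-17 0
0.19679058348750939 0 0 0 0 0
0 0.62640249952381899 0 2.7755575615628914e-17 0 0
0 0 0 5.5511151231257827e-17 0 0.19679058348750939
0 0 0 0 4.163336342344337e-17 0
0.62170676311493134 0 0 0 0 0
0.19679058348750939 0 2.7755575615628914e-17 0 0 0
0 0 0 4.163336342344337e-17 0 0.62170676311493134
0 0 0 0 0 0.19679058348750939
0 2.7755575615628914e-17 0 0 0.19679058348750933 0
0 0 0 0 0.62170676311493156 0
-1.6653345369377348e-16 0 0 0 0 0
0 0 0 0.19679058348750933 0 0
0 0 0 0.62170676311493156 0 -1.6653345369377348e-16
0 0 0 0 0.19679058348750936 0
-1.1102230246251565e-16 0 0 0 0 0
-1.6653345369377348e-16 0 0.6530707469374234 0 0 0
0 0 0 0.19679058348750936 0 -1.1102230246251565e-16
0 0 0 0 0 -1.6653345369377348e-16
0 0.6530707469374234 0 0 0 0
0 0 0 0 0 0
0.19679058348750933 0 0 0 0 0
0.62170676311493156 0 -1.6653345369377348e-16 0 0 0
0 0 0 0 0 0.19679058348750933
0 0 0 0 0 0.62170676311493156
0 -1.6653345369377348e-16 0 0 0 0
0.19679058348750936 0 -1.1102230246251565e-16 0 0 0
0 0 -1.6653345369377348e-16 0 0.6530707469374234 0
0 0 0 0 0 0.19679058348750936
0 -1.1102230246251565e-16 0 0 0 0
0 -1.6653345369377348e-16 0 0.6530707469374234
mo_coefficients 2 2
0.57802798202349037 0.57802798202349059 -0.99650311975788675 0.99650311975788664
overlap 2 2
1 0.49648469160444758 0.49648469160444758 1
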