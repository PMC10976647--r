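# fsvqe molecular integral fixture v1
molecule H2
basis_label STO-3G
geometry_id 1.5
n_spin_orbitals 4
n_electrons 2
e_nuclear 0.35278480726866668
hf_energy -0.91087355457996322
one_body 4 4
-0.90818087245276091 0 7.4249146219797072e-17 0 0 -0.90818087245276091
0 7.4249146219797072e-17 -3.3468937419629001e-17 0 -0.66533693576747766 0
0 -3.3468937419629001e-17 0 -0.66533693576747766
two_body 4 4 4 4
0.55270338305689182 0 -4.163336342344337e-17 0 0 0
0 0 2.7755575615628914e-17 0 0.22953593606280775 0
0 0 0 0 0 0.55270338305689182
0 -4.163336342344337e-17 0 0 0 0
0 2.7755575615628914e-17 0 0.22953593606280775 0 0
0 0 -2.7755575615628914e-17 0 0.55968415560817464 0
0 0 0 0 0.22953593606280775 0
1.1102230246251565e-16 0 0 0 0 0
0 -2.7755575615628914e-17 0 0.55968415560817464 0 0
0 0 0 0.22953593606280775 0 1.1102230246251565e-16
0 0 0 0 0 0
0 0 0.55270338305689182 0 -4.163336342344337e-17 0
0 0 0 0 2.7755575615628914e-17 0
0.22953593606280775 0 0 0 0 0
0 0.55270338305689182 0 -4.163336342344337e-17 0 0
0 0 0 2.7755575615628914e-17 0 0.22953593606280775
0 0 0 0 -2.7755575615628914e-17 0
0.55968415560817464 0 0 0 0 0
0.22953593606280775 0 1.1102230246251565e-16 0 0 0
0 0 0 -2.7755575615628914e-17 0 0.55968415560817464
0 0 0 0 0 0.22953593606280775
0 1.1102230246251565e-16 -5.5511151231257827e-17 0 0.2295359360628077 0
0 0 0 0 0.55968415560817464 0
2.7755575615628914e-17 0 0 0 0 0
0 -5.5511151231257827e-17 0 0.2295359360628077 0 0
0 0 0 0.55968415560817464 0 2.7755575615628914e-17
0 0 0 0 0.22953593606280775 0
5.5511151231257827e-17 0 0 0 0 0
2.7755575615628914e-17 0 0.58342076119804376 0 0 0
0 0 0 0.22953593606280775 0 5.5511151231257827e-17
0 0 0 0 0 2.7755575615628914e-17
0 0.58342076119804376 0 0 0 0
0 0 0 0 -5.5511151231257827e-17 0
0.2295359360628077 0 0 0 0 0
0.55968415560817464 0 2.7755575615628914e-17 0 0 0
0 0 0 -5.5511151231257827e-17 0 0.2295359360628077
0 0 0 0 0 0.55968415560817464
0 2.7755575615628914e-17 0 0 0 0
0.22953593606280775 0 5.5511151231257827e-17 0 0 0
0 0 2.7755575615628914e-17 0 0.58342076119804376 0
0 0 0 0 0 0.22953593606280775
0 5.5511151231257827e-17 0 0 0 0
0 2.7755575615628914e-17 0 0.58342076119804376
mo_coefficients 2 2
0.63074566873782023 0.63074566873782012 -0.82021585388468488 0.82021585388468499
overlap 2 2
1 0.25678633631925718 0.25678633631925718 1
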