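# fsvqe molecular integral fixture v1
molecule H2
basis_label STO-3G
geometry_id 0.74
n_spin_orbitals 4
n_electrons 2
e_nuclear 0.71510433905810811
hf_energy -1.1167593073952005
one_body 4 4
-1.2533097866316096 0 -4.3519710495377106e-17 0 0 -1.2533097866316096
0 -4.3519710495377106e-17 3.3758079361350153e-16 0 -0.47506884878720029 0
0 3.3758079361350153e-16 0 -0.47506884878720029
two_body 4 4 4 4
0.67475592680991037 0 -1.3877787807814457e-17 0 0 0
0 0 -8.3266726846886741e-17 0 0.18121046201653132 0
0 0 0 0 0 0.67475592680991037
0 -1.3877787807814457e-17 0 0 0 0
0 -8.3266726846886741e-17 0 0.18121046201653132 0 0
0 0 -2.0816681711721685e-17 0 0.66371140134667583 0
0 0 0 0 0.18121046201653102 0
0 0 0 0 0 0
0 -2.0816681711721685e-17 0 0.66371140134667583 0 0
0 0 0 0.18121046201653102 0 0
0 0 0 0 0 0
0 0 0.67475592680991037 0 -1.3877787807814457e-17 0
0 0 0 0 -8.3266726846886741e-17 0
0.18121046201653132 0 0 0 0 0
0 0.67475592680991037 0 -1.3877787807814457e-17 0 0
0 0 0 -8.3266726846886741e-17 0 0.18121046201653132
0 0 0 0 -2.0816681711721685e-17 0
0.66371140134667583 0 0 0 0 0
0.18121046201653102 0 0 0 0 0
0 0 0 -2.0816681711721685e-17 0 0.66371140134667583
0 0 0 0 0 0.18121046201653102
0 0 -1.1102230246251565e-16 0 0.18121046201653143 0
0 0 0 0 0.66371140134667628 0
-3.3306690738754696e-16 0 0 0 0 0
0 -1.1102230246251565e-16 0 0.18121046201653143 0 0
0 0 0 0.66371140134667628 0 -3.3306690738754696e-16
0 0 0 0 0.18121046201653093 0
2.2204460492503131e-16 0 0 0 0 0
-8.3266726846886741e-17 0 0.6976515044860705 0 0 0
0 0 0 0.18121046201653093 0 2.2204460492503131e-16
0 0 0 0 0 -8.3266726846886741e-17
0 0.6976515044860705 0 0 0 0
0 0 0 0 -1.1102230246251565e-16 0
0.18121046201653143 0 0 0 0 0
0.66371140134667628 0 -3.3306690738754696e-16 0 0 0
0 0 0 -1.1102230246251565e-16 0 0.18121046201653143
0 0 0 0 0 0.66371140134667628
0 -3.3306690738754696e-16 0 0 0 0
0.18121046201653093 0 2.2204460492503131e-16 0 0 0
0 0 -8.3266726846886741e-17 0 0.6976515044860705 0
0 0 0 0 0 0.18121046201653093
0 2.2204460492503131e-16 0 0 0 0
0 -8.3266726846886741e-17 0 0.6976515044860705
mo_coefficients 2 2
0.54884227509126959 0.54884227509126937 -1.2124519201518078 1.2124519201518078
overlap 2 2
1 0.6598731217571141 0.6598731217571141 1
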