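# fsvqe molecular integral fixture v1
molecule H2
basis_label STO-3G
geometry_id 0.5
n_spin_orbitals 4
n_electrons 2
e_nuclear 1.0583544218060001
hf_energy -1.0429962745544585
one_body 4 4
-1.4105283677069111 0 -5.2632966354730567e-17 0 0 -1.4105283677069111
0 -5.2632966354730567e-17 2.2346503243433459e-16 0 -0.25693578241687537 0
0 2.2346503243433459e-16 0 -0.25693578241687537
two_body 4 4 4 4
0.71970603905336361 0 -1.3877787807814457e-16 0 0 0
0 0 -3.1918911957973251e-16 0 0.16887022769047993 0
0 0 0 0 0 0.71970603905336361
0 -1.3877787807814457e-16 0 0 0 0
0 -3.1918911957973251e-16 0 0.16887022769047993 0 0
0 0 -3.677613769070831e-16 0 0.70723984154152708 0
0 0 0 0 0.16887022769047993 0
7.7715611723760958e-16 0 0 0 0 0
0 -3.677613769070831e-16 0 0.70723984154152708 0 0
0 0 0 0.16887022769047993 0 7.7715611723760958e-16
0 0 0 0 0 0
0 0 0.71970603905336361 0 -1.3877787807814457e-16 0
0 0 0 0 -3.1918911957973251e-16 0
0.16887022769047993 0 0 0 0 0
0 0.71970603905336361 0 -1.3877787807814457e-16 0 0
0 0 0 -3.1918911957973251e-16 0 0.16887022769047993
0 0 0 0 -3.677613769070831e-16 0
0.70723984154152708 0 0 0 0 0
0.16887022769047993 0 7.7715611723760958e-16 0 0 0
0 0 0 -3.677613769070831e-16 0 0.70723984154152708
0 0 0 0 0 0.16887022769047993
0 7.7715611723760958e-16 -2.2204460492503131e-16 0 0.16887022769048002 0
0 0 0 0 0.70723984154152786 0
5.5511151231257827e-16 0 0 0 0 0
0 -2.2204460492503131e-16 0 0.16887022769048002 0 0
0 0 0 0.70723984154152786 0 5.5511151231257827e-16
0 0 0 0 0.16887022769047952 0
2.2204460492503131e-16 0 0 0 0 0
1.6653345369377348e-16 0 0.74483937036656478 0 0 0
0 0 0 0.16887022769047952 0 2.2204460492503131e-16
0 0 0 0 0 1.6653345369377348e-16
0 0.74483937036656478 0 0 0 0
0 0 0 0 -2.2204460492503131e-16 0
0.16887022769048002 0 0 0 0 0
0.70723984154152786 0 5.5511151231257827e-16 0 0 0
0 0 0 -2.2204460492503131e-16 0 0.16887022769048002
0 0 0 0 0 0.70723984154152786
0 5.5511151231257827e-16 0 0 0 0
0.16887022769047952 0 2.2204460492503131e-16 0 0 0
0 0 1.6653345369377348e-16 0 0.74483937036656478 0
0 0 0 0 0 0.16887022769047952
0 2.2204460492503131e-16 0 0 0 0
0 1.6653345369377348e-16 0 0.74483937036656478
mo_coefficients 2 2
0.5249046467938 0.52490464679379878 -1.6427387333685066 1.6427387333685068
overlap 2 2
1 0.81471809396171613 0.81471809396171613 1
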