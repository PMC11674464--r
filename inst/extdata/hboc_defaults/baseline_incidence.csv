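organ,age,hazard
breast,0,5e-6
breast,1,5e-6
breast,2,5e-6
breast,3,5e-6
breast,4,5e-6
breast,5,5e-6
breast,6,5e-6
breast,7,5e-6
breast,8,5e-6
breast,9,5e-6
breast,10,5e-6
breast,11,5e-6
breast,12,5e-6
breast,13,5e-6
breast,14,5e-6
breast,15,5e-6
breast,16,5e-6
breast,17,5e-6
breast,18,5e-6
breast,19,5e-6
breast,20,6.002e-5
breast,21,6.002e-5
breast,22,6.002e-5
breast,23,6.002e-5
breast,24,6.002e-5
breast,25,2.2021e-4
breast,26,2.2021e-4
breast,27,2.2021e-4
breast,28,2.2021e-4
breast,29,2.2021e-4
breast,30,6.0181e-4
breast,31,6.0181e-4
breast,32,6.0181e-4
breast,33,6.0181e-4
breast,34,6.0181e-4
breast,35,0.00131016
breast,36,0.00131016
breast,37,0.00131016
breast,38,0.00131016
breast,39,0.00131016
breast,40,0.00182835
breast,41,0.00182835
breast,42,0.00182835
breast,43,0.00182835
breast,44,0.00182835
breast,45,0.00225759
breast,46,0.00225759
breast,47,0.00225759
breast,48,0.00225759
breast,49,0.00225759
breast,50,0.00301539
breast,51,0.00301539
breast,52,0.00301539
breast,53,0.00301539
breast,54,0.00301539
breast,55,0.00338096
breast,56,0.00338096
breast,57,0.00338096
breast,58,0.00338096
breast,59,0.00338096
breast,60,0.00398184
breast,61,0.00398184
breast,62,0.00398184
breast,63,0.00398184
breast,64,0.00398184
breast,65,0.00395183
breast,66,0.00395183
breast,67,0.00395183
breast,68,0.00395183
breast,69,0.00395183
breast,70,0.00448449
breast,71,0.00448449
breast,72,0.00448449
breast,73,0.00448449
breast,74,0.00448449
breast,75,0.00435547
breast,76,0.00435547
breast,77,0.00435547
breast,78,0.00435547
breast,79,0.00435547
breast,80,0.00350681
breast,81,0.00350681
breast,82,0.00350681
breast,83,0.00350681
breast,84,0.00350681
breast,85,0.00237251
breast,86,0.00237251
breast,87,0.00237251
breast,88,0.00237251
breast,89,0.00237251
breast,90,0.00120049
breast,91,0.00120049
breast,92,0.00120049
breast,93,0.00120049
breast,94,0.00120049
breast,95,0.00120049
breast,96,0.00120049
breast,97,0.00120049
breast,98,0.00120049
breast,99,0.00120049
breast,100,0.00120049
ovary,0,3.33e-6
ovary,1,3.33e-6
ovary,2,3.33e-6
ovary,3,3.33e-6
ovary,4,3.33e-6
ovary,5,3.33e-6
ovary,6,3.33e-6
ovary,7,3.33e-6
ovary,8,3.33e-6
ovary,9,3.33e-6
ovary,10,3.33e-6
ovary,11,3.33e-6
ovary,12,3.33e-6
ovary,13,3.33e-6
ovary,14,3.33e-6
ovary,15,3.33e-6
ovary,16,3.33e-6
ovary,17,3.33e-6
ovary,18,3.33e-6
ovary,19,3.33e-6
ovary,20,3.33e-6
ovary,21,3.33e-6
ovary,22,3.33e-6
ovary,23,3.33e-6
ovary,24,3.33e-6
ovary,25,3.33e-6
ovary,26,3.33e-6
ovary,27,3.33e-6
ovary,28,3.33e-6
ovary,29,3.33e-6
ovary,30,4.001e-5
ovary,31,4.001e-5
ovary,32,4.001e-5
ovary,33,4.001e-5
ovary,34,4.001e-5
ovary,35,4.001e-5
ovary,36,4.001e-5
ovary,37,4.001e-5
ovary,38,4.001e-5
ovary,39,4.001e-5
ovary,40,1.1012e-4
ovary,41,1.1012e-4
ovary,42,1.1012e-4
ovary,43,1.1012e-4
ovary,44,1.1012e-4
ovary,45,1.1012e-4
ovary,46,1.1012e-4
ovary,47,1.1012e-4
ovary,48,1.1012e-4
ovary,49,1.1012e-4
ovary,50,2.206e-4
ovary,51,2.206e-4
ovary,52,2.206e-4
ovary,53,2.206e-4
ovary,54,2.206e-4
ovary,55,2.206e-4
ovary,56,2.206e-4
ovary,57,2.206e-4
ovary,58,2.206e-4
ovary,59,2.206e-4
ovary,60,3.3181e-4
ovary,61,3.3181e-4
ovary,62,3.3181e-4
ovary,63,3.3181e-4
ovary,64,3.3181e-4
ovary,65,3.3181e-4
ovary,66,3.3181e-4
ovary,67,3.3181e-4
ovary,68,3.3181e-4
ovary,69,3.3181e-4
ovary,70,3.2281e-4
ovary,71,3.2281e-4
ovary,72,3.2281e-4
ovary,73,3.2281e-4
ovary,74,3.2281e-4
ovary,75,3.2281e-4
ovary,76,3.2281e-4
ovary,77,3.2281e-4
ovary,78,3.2281e-4
ovary,79,3.2281e-4
ovary,80,2.0229e-4
ovary,81,2.0229e-4
ovary,82,2.0229e-4
ovary,83,2.0229e-4
ovary,84,2.0229e-4
ovary,85,2.0229e-4
ovary,86,2.0229e-4
ovary,87,2.0229e-4
ovary,88,2.0229e-4
ovary,89,2.0229e-4
ovary,90,7.09e-5
ovary,91,7.09e-5
ovary,92,7.09e-5
ovary,93,7.09e-5
ovary,94,7.09e-5
ovary,95,7.09e-5
ovary,96,7.09e-5
ovary,97,7.09e-5
ovary,98,7.09e-5
ovary,99,7.09e-5
ovary,100,7.09e-5
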