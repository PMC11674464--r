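sex,age,qx
F,0,0.004
F,1,1e-4
F,2,1e-4
F,3,1e-4
F,4,1e-4
F,5,1e-4
F,6,1e-4
F,7,1e-4
F,8,1e-4
F,9,1e-4
F,10,1e-4
F,11,2.254e-4
F,12,2.282e-4
F,13,2.313e-4
F,14,2.348e-4
F,15,2.386e-4
F,16,2.429e-4
F,17,2.477e-4
F,18,2.53e-4
F,19,2.588e-4
F,20,2.653e-4
F,21,2.726e-4
F,22,2.806e-4
F,23,2.895e-4
F,24,2.994e-4
F,25,3.104e-4
F,26,3.227e-4
F,27,3.362e-4
F,28,3.513e-4
F,29,3.681e-4
F,30,3.867e-4
F,31,4.074e-4
F,32,4.303e-4
F,33,4.558e-4
F,34,4.841e-4
F,35,5.156e-4
F,36,5.505e-4
F,37,5.893e-4
F,38,6.324e-4
F,39,6.803e-4
F,40,7.335e-4
F,41,7.926e-4
F,42,8.582e-4
F,43,9.31e-4
F,44,0.001012
F,45,0.0011018
F,46,0.0012017
F,47,0.0013126
F,48,0.0014358
F,49,0.0015726
F,50,0.0017245
F,51,0.0018933
F,52,0.0020808
F,53,0.002289
F,54,0.0025203
F,55,0.0027772
F,56,0.0030625
F,57,0.0033794
F,58,0.0037314
F,59,0.0041223
F,60,0.0045566
F,61,0.0050389
F,62,0.0055746
F,63,0.0061696
F,64,0.0068305
F,65,0.0075646
F,66,0.00838
F,67,0.0092856
F,68,0.0102914
F,69,0.0114087
F,70,0.0126496
F,71,0.0140279
F,72,0.0155588
F,73,0.0172591
F,74,0.0191478
F,75,0.0212455
F,76,0.0235754
F,77,0.0261634
F,78,0.0290378
F,79,0.0322304
F,80,0.0357765
F,81,0.0397152
F,82,0.04409
F,83,0.0489491
F,84,0.0543461
F,85,0.0603407
F,86,0.0669989
F,87,0.0743942
F,88,0.0826083
F,89,0.0917318
F,90,0.1018653
F,91,0.1131208
F,92,0.1256223
F,93,0.1395079
F,94,0.1549307
F,95,0.172061
F,96,0.1910879
F,97,0.2122212
F,98,0.2356942
F,99,0.2617659
F,100,0.290724
M,0,0.005
M,1,1.5e-4
M,2,1.5e-4
M,3,1.5e-4
M,4,1.5e-4
M,5,1.5e-4
M,6,1.5e-4
M,7,1.5e-4
M,8,1.5e-4
M,9,1.5e-4
M,10,1.5e-4
M,11,4.497e-4
M,12,4.551e-4
M,13,4.61e-4
M,14,4.677e-4
M,15,4.75e-4
M,16,4.831e-4
M,17,4.922e-4
M,18,5.022e-4
M,19,5.132e-4
M,20,5.255e-4
M,21,5.392e-4
M,22,5.543e-4
M,23,5.71e-4
M,24,5.895e-4
M,25,6.101e-4
M,26,6.329e-4
M,27,6.582e-4
M,28,6.862e-4
M,29,7.172e-4
M,30,7.516e-4
M,31,7.898e-4
M,32,8.321e-4
M,33,8.789e-4
M,34,9.309e-4
M,35,9.885e-4
M,36,0.0010524
M,37,0.0011231
M,38,0.0012016
M,39,0.0012885
M,40,0.0013849
M,41,0.0014918
M,42,0.0016103
M,43,0.0017416
M,44,0.0018871
M,45,0.0020484
M,46,0.0022273
M,47,0.0024255
M,48,0.0026453
M,49,0.0028889
M,50,0.0031589
M,51,0.0034582
M,52,0.00379
M,53,0.0041578
M,54,0.0045655
M,55,0.0050174
M,56,0.0055184
M,57,0.0060737
M,58,0.0066892
M,59,0.0073715
M,60,0.0081279
M,61,0.0089663
M,62,0.0098956
M,63,0.0109258
M,64,0.0120678
M,65,0.0133337
M,66,0.0147369
M,67,0.0162923
M,68,0.0180165
M,69,0.0199277
M,70,0.0220463
M,71,0.0243947
M,72,0.0269979
M,73,0.0298836
M,74,0.0330823
M,75,0.036628
M,76,0.0405585
M,77,0.0449153
M,78,0.0497449
M,79,0.0550983
M,80,0.0610326
M,81,0.0676108
M,82,0.0749026
M,83,0.0829854
M,84,0.0919453
M,85,0.1018771
M,86,0.1128865
M,87,0.1250903
M,88,0.1386182
M,89,0.1536137
M,90,0.170236
M,91,0.1886618
M,92,0.2090866
M,93,0.2317273
M,94,0.2568243
M,95,0.2846441
M,96,0.3154822
M,97,0.3496659
M,98,0.3875582
M,99,0.4295616
M,100,0.4761219
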